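# Desk-scale genotype demultiplexer: binomial-mixture EM over per-cell
# ref/alt counts at SNP loci, with uniform mixing weights. Stands in for an
# external SNP demultiplexer; real cluster tables and cluster-genotype VCFs
# can be ingested instead via read_souporcell_clusters()/read_cluster_genotypes_vcf().

#' Cluster cells by genotype with a binomial-mixture EM
#'
#' Models each cell's alt-read count at locus l, given cluster k, as
#' Binomial(depth, q\[l,k\]) and maximizes the total log-likelihood
#' `sum_l a*log(q) + r*log(1-q)` over covered loci by EM with uniform
#' mixing weights. The M-step sets q to the responsibility-weighted alt
#' fraction, clipped to `[error_rate, 1 - error_rate]`. The first restart is
#' seeded k-means++-style on per-cell alt-fraction vectors (missing loci
#' mean-imputed); remaining restarts use random cells as seeds. The best
#' restart by final log-likelihood wins; ties break to the lower restart
#' index. Cells with zero covered loci are reported `unassigned`.
#'
#' @param ref,alt Sparse (or dense) loci-x-cells count matrices with matching
#'   dimnames.
#' @param K Number of genotype clusters (the number of pooled samples).
#' @param n_restarts EM restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 100).
#' @param tol Convergence tolerance on the total log-likelihood (default 1e-4).
#' @param error_rate Clipping bound for q (default 0.01).
#' @param seed Integer seed making the fit deterministic.
#' @return A `genotype_fit`: list with `K`, `allele_fraction` (loci x K),
#'   `log_likelihood`, `ll_trace`, `assignment` (tibble `barcode`, `status`,
#'   `cluster`, per-cluster log-likelihood columns), `ref`, `alt`.
#' @export
fit_genotype_clusters <- function(ref, alt, K, n_restarts = 5L, max_iter = 100L,
                                  tol = 1e-4, error_rate = 0.01, seed = 1L) {
  stopifnot(all(dim(ref) == dim(alt)))
  if (K < 1) abort("K must be >= 1")
  ref <- as(ref, "CsparseMatrix"); alt <- as(alt, "CsparseMatrix")
  depth <- ref + alt
  covered <- unname(Matrix::colSums(depth) > 0)
  if (sum(covered) < K) abort("K exceeds the number of cells with nonzero coverage")
  barcodes <- colnames(ref)
  if (is.null(barcodes)) barcodes <- sprintf("cell%05d", seq_len(ncol(ref)))

  R <- as.matrix(ref[, covered, drop = FALSE])
  A <- as.matrix(alt[, covered, drop = FALSE])
  L <- nrow(R); n <- ncol(R)
  eps <- error_rate

  # per-cell alt fractions, missing loci imputed with the locus mean
  frac <- A / (A + R)
  locus_mean <- rowMeans(frac, na.rm = TRUE)
  locus_mean[is.nan(locus_mean)] <- 0.5
  frac_imp <- frac
  for (l in seq_len(L)) frac_imp[l, is.na(frac_imp[l, ])] <- locus_mean[l]

  cell_ll <- function(q) {
    # n x K matrix of per-cell log-likelihoods under each cluster profile
    crossprod(A, log(q)) + crossprod(R, log(1 - q))
  }
  m_step <- function(resp) {
    q <- (A %*% resp) / ((A + R) %*% resp + 1e-300)
    pmin(pmax(as.matrix(q), eps), 1 - eps)
  }

  kmeanspp_centers <- function() {
    centers <- integer(K)
    centers[1] <- sample.int(n, 1L)
    if (K > 1) for (j in 2:K) {
      d2 <- vapply(seq_len(n), function(c) {
        min(colSums((frac_imp[, centers[seq_len(j - 1)], drop = FALSE] - frac_imp[, c])^2))
      }, numeric(1))
      if (sum(d2) == 0) d2 <- rep(1, n)
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    centers
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- if (r == 1L) kmeanspp_centers() else sample.int(n, K)
    q <- pmin(pmax(frac_imp[, centers, drop = FALSE] * 0.8 + 0.1, eps), 1 - eps)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      ll_ck <- cell_ll(q)
      mx <- apply(ll_ck, 1L, max)
      resp <- exp(ll_ck - mx)
      tot <- mx + log(rowSums(resp)) - log(K)
      resp <- resp / rowSums(resp)
      ll <- sum(tot)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
      q <- m_step(resp)
    }
    if (is.null(best) || ll > best$ll + 1e-9) {
      best <- list(q = q, ll = ll, ll_trace = ll_trace, ll_ck = ll_ck)
    }
  }

  colnames(best$q) <- as.character(seq_len(K) - 1L)
  hard <- max.col(best$ll_ck, ties.method = "first") - 1L

  singlet_ll <- matrix(NA_real_, length(barcodes), K,
                       dimnames = list(NULL, paste0("cluster", seq_len(K) - 1L)))
  singlet_ll[covered, ] <- best$ll_ck
  assignment <- tibble(
    barcode = barcodes,
    status = ifelse(covered, "singlet", "unassigned"),
    cluster = ifelse(covered, replace(rep(NA_integer_, length(barcodes)), covered, hard),
                     NA_integer_)
  )
  assignment <- bind_cols(assignment, as_tibble(singlet_ll))

  structure(
    list(
      K = K,
      allele_fraction = best$q,
      log_likelihood = best$ll,
      ll_trace = best$ll_trace,
      assignment = assignment,
      error_rate = eps,
      ref = ref, alt = alt
    ),
    class = "genotype_fit"
  )
}

#' @export
print.genotype_fit <- function(x, ...) {
  cat(sprintf(
    "<genotype_fit: K = %d, %d cells (%d unassigned), log-likelihood %.1f>\n",
    x$K, nrow(x$assignment), sum(x$assignment$status == "unassigned"),
    x$log_likelihood
  ))
  invisible(x)
}

#' @export
tidy.genotype_fit <- function(x, ...) {
  x$assignment
}

#' @export
glance.genotype_fit <- function(x, ...) {
  tibble(
    K = x$K,
    n_cells = nrow(x$assignment),
    n_unassigned = sum(x$assignment$status == "unassigned"),
    n_doublet = sum(x$assignment$status == "doublet"),
    log_likelihood = x$log_likelihood,
    n_iter = length(x$ll_trace)
  )
}

#' Plot per-cluster allele-fraction profiles of a genotype fit
#'
#' @param object A `genotype_fit`.
#' @param ... Unused.
#' @return A ggplot histogram of cluster allele fractions, faceted by
#'   cluster; well-separated genotypes show the characteristic three-mode
#'   shape near the error rate, 0.5 and one minus the error rate.
#' @export
autoplot.genotype_fit <- function(object, ...) {
  df <- as_tibble(object$allele_fraction) |>
    mutate(locus = dplyr::row_number()) |>
    tidyr::pivot_longer(-"locus", names_to = "cluster", values_to = "q")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "cluster allele fraction q", y = "loci") +
    ggplot2::theme_minimal()
}

#' Flag cross-genotype doublets against a fitted cluster model
#'
#' For every covered cell, compares the best singlet log-likelihood with the
#' best two-cluster mixture log-likelihood, where the mixture profile is the
#' average of the two cluster allele-fraction profiles. A cell is called a
#' doublet when the mixture beats the singlet by more than `margin` nats;
#' the recorded pair is the argmax mixture.
#'
#' @param fit A `genotype_fit` with `K >= 2`.
#' @param margin Doublet log-likelihood margin in nats (default 2).
#' @return The fit's assignment tibble with updated `status` (`doublet`
#'   where called), `cluster` pair rendered `"i/j"`, and columns
#'   `log_prob_singleton`, `log_prob_doublet`.
#' @export
call_doublets <- function(fit, margin = 2) {
  stopifnot(inherits(fit, "genotype_fit"))
  if (fit$K < 2) abort("doublet calling needs K >= 2 (no cluster pairs exist)")
  q <- fit$allele_fraction
  K <- fit$K
  depth <- fit$ref + fit$alt
  covered <- unname(Matrix::colSums(depth) > 0)
  A <- as.matrix(fit$alt[, covered, drop = FALSE])
  R <- as.matrix(fit$ref[, covered, drop = FALSE])

  pairs <- utils::combn(K, 2L)
  qmix <- (q[, pairs[1L, ], drop = FALSE] + q[, pairs[2L, ], drop = FALSE]) / 2
  ll_mix <- crossprod(A, log(qmix)) + crossprod(R, log(1 - qmix))
  ll_sing <- crossprod(A, log(q)) + crossprod(R, log(1 - q))

  best_sing <- unname(apply(ll_sing, 1L, max))
  sing_k <- max.col(ll_sing, ties.method = "first") - 1L
  best_mix <- unname(apply(ll_mix, 1L, max))
  mix_j <- max.col(ll_mix, ties.method = "first")
  pair_lbl <- paste0(pairs[1L, mix_j] - 1L, "/", pairs[2L, mix_j] - 1L)

  is_dbl <- (best_mix - best_sing) > margin
  out <- fit$assignment
  idx <- which(covered)
  out$status[idx] <- ifelse(is_dbl, "doublet", "singlet")
  out$assignment <- NA_character_
  out$assignment[idx] <- ifelse(is_dbl, pair_lbl, as.character(sing_k))
  out$cluster[idx] <- ifelse(is_dbl, NA_integer_, sing_k)
  out$log_prob_singleton <- NA_real_
  out$log_prob_singleton[idx] <- best_sing
  out$log_prob_doublet <- NA_real_
  out$log_prob_doublet[idx] <- best_mix
  out |> select("barcode", "status", "assignment", "cluster",
                "log_prob_singleton", "log_prob_doublet", dplyr::starts_with("cluster"))
}

#' Discretize cluster allele fractions into consensus genotype calls
#'
#' Maps each cluster's allele fraction q at each locus to a genotype call:
#' `q < hom_threshold` gives 0, `q > 1 - hom_threshold` gives 1,
#' `|q - 0.5| < het_band` gives 0.5, anything else (or a locus whose
#' aggregate read coverage in the cluster's singlet cells falls below
#' `min_reads`) is a no-call (`NA`).
#'
#' @param fit A `genotype_fit`.
#' @param assignment Optional assignment tibble (e.g. from [call_doublets()])
#'   defining which cells are singlets of each cluster; defaults to the
#'   fit's own assignment.
#' @param hom_threshold Homozygous call band (default 0.1).
#' @param het_band Half-width of the heterozygous band around 0.5
#'   (default 0.15).
#' @param min_reads Minimum aggregate reads per locus per cluster
#'   (default 3).
#' @return A loci x K numeric matrix with entries 0, 0.5, 1 or `NA`.
#' @export
consensus_genotypes <- function(fit, assignment = NULL, hom_threshold = 0.1,
                                het_band = 0.15, min_reads = 3L) {
  stopifnot(inherits(fit, "genotype_fit"))
  if (hom_threshold >= 0.5 - het_band) {
    abort("overlapping bands: need hom_threshold < 0.5 - het_band")
  }
  if (is.null(assignment)) assignment <- fit$assignment
  q <- fit$allele_fraction
  calls <- matrix(NA_real_, nrow(q), ncol(q), dimnames = dimnames(q))
  calls[q < hom_threshold] <- 0
  calls[q > 1 - hom_threshold] <- 1
  calls[abs(q - 0.5) < het_band] <- 0.5

  depth <- fit$ref + fit$alt
  for (k in seq_len(fit$K)) {
    cells <- assignment$barcode[assignment$status == "singlet" &
                                  !is.na(assignment$cluster) &
                                  assignment$cluster == k - 1L]
    cov_k <- if (length(cells)) {
      Matrix::rowSums(depth[, colnames(depth) %in% cells, drop = FALSE])
    } else {
      rep(0, nrow(depth))
    }
    calls[cov_k < min_reads, k] <- NA_real_
  }
  rownames(calls) <- rownames(fit$ref)
  calls
}
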