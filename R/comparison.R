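.pairs_within <- function(idx) {
  if (length(idx) < 2) return(matrix(integer(0), ncol = 2))
  t(utils::combn(idx, 2))
}

#' Permutation test for shared contigs between virome groups
#'
#' Tests whether viromes within a group share more sequence content than
#' viromes between groups. Shared content between an ordered virome pair is
#' the fraction of `n_sampled` randomly sampled contigs of the first virome
#' with at least one similarity hit (`e_value < e_value_max`) in the
#' second.
#'
#' Two schemes are provided:
#' \describe{
#'   \item{`"paired"`}{per iteration, draw one random within-group pair and
#'     one random between-group pair, recompute both shared fractions on
#'     fresh contig samples, and count how often the between-group value is
#'     at least the within-group value; the empirical p-value is that
#'     fraction over `B` iterations. This mirrors reporting of group means
#'     over resampled iterations.}
#'   \item{`"label_perm"`}{the observed statistic is the mean within-group
#'     shared fraction minus the mean between-group shared fraction over
#'     all admissible pairs; the null distribution is obtained by permuting
#'     group labels `B` times, and `p = (1 + #\{null >= observed\}) /
#'     (B + 1)`. Under a label-exchangeable null this p-value is
#'     approximately uniform.}
#' }
#' The comparison uses `>=`, which is conservative. When `subjects` labels
#' are supplied, between-group pairs from the same subject are excluded.
#'
#' @param viromes named list of contig sets (named character vectors or
#'   `assembly_result` objects).
#' @param groups factor or character vector (length of `viromes`) with
#'   exactly two levels; the first level is the focal group whose
#'   within-group sharing is tested.
#' @param subjects optional subject labels for intra-subject exclusion.
#' @param B iterations (default 10000).
#' @param n_sampled contigs sampled per shared-fraction evaluation
#'   (default 1000).
#' @param e_value_max similarity threshold (default `1e-10`).
#' @param min_frac_shorter minimum aligned fraction of the shorter sequence.
#' @param scheme `"paired"` (default) or `"label_perm"`.
#' @param seed integer seed.
#' @param indicators optional precomputed [shared_contig_indicators()];
#'   computed from `viromes` when missing.
#' @return a `permutation_result`: a list with `observed_stat`,
#'   `null_stats`, `p_value`, `within_mean`, `within_sd`, `between_mean`,
#'   `between_sd`, `scheme`, `B`, `n_sampled` and `seed`.
#' @export
permutation_shared_test <- function(viromes, groups, subjects = NULL,
                                    B = 10000, n_sampled = 1000,
                                    e_value_max = 1e-10,
                                    min_frac_shorter = 0.50,
                                    scheme = c("paired", "label_perm"),
                                    seed = 1, indicators = NULL) {
  scheme <- match.arg(scheme)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || length(groups) != length(viromes)) {
    stop("groups must label each virome with exactly two levels")
  }
  if (any(table(groups) < 2)) {
    stop("need at least two viromes per group")
  }
  if (is.null(indicators)) {
    indicators <- shared_contig_indicators(
      viromes, e_value_max = e_value_max,
      min_frac_shorter = min_frac_shorter)
  }
  n <- length(indicators)
  focal <- levels(groups)[1]
  idx_a <- which(groups == focal)
  idx_b <- which(groups != focal)

  within <- .pairs_within(idx_a)
  between <- as.matrix(expand.grid(idx_a, idx_b))
  if (!is.null(subjects)) {
    keep <- subjects[between[, 1]] != subjects[between[, 2]]
    between <- between[keep, , drop = FALSE]
    keep_w <- subjects[within[, 1]] != subjects[within[, 2]]
    within <- within[keep_w, , drop = FALSE]
  }
  if (nrow(within) == 0 || nrow(between) == 0) {
    stop("no admissible within- or between-group pairs")
  }

  set.seed(derive_seed(seed, "comparison"))
  frac_of <- function(i, j) {
    ind <- indicators[[i]][[j]]
    pick <- sample.int(length(ind), n_sampled,
                       replace = n_sampled > length(ind))
    mean(ind[pick])
  }
  orient <- function(pair) {
    if (stats::runif(1) < 0.5) pair else rev(pair)
  }

  if (scheme == "paired") {
    w_stats <- numeric(B)
    b_stats <- numeric(B)
    for (b in seq_len(B)) {
      wp <- orient(within[sample.int(nrow(within), 1), ])
      bp <- orient(between[sample.int(nrow(between), 1), ])
      w_stats[b] <- frac_of(wp[1], wp[2])
      b_stats[b] <- frac_of(bp[1], bp[2])
    }
    p <- mean(b_stats >= w_stats)
    res <- list(observed_stat = mean(w_stats), null_stats = b_stats,
                p_value = p, within_mean = mean(w_stats),
                within_sd = sd(w_stats), between_mean = mean(b_stats),
                between_sd = sd(b_stats))
  } else {
    # fixed per-ordered-pair fractions, then label permutation
    frac <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) frac[i, j] <- frac_of(i, j)
    }
    pair_mean <- function(pairs) {
      mean(vapply(seq_len(nrow(pairs)), function(r) {
        (frac[pairs[r, 1], pairs[r, 2]] + frac[pairs[r, 2], pairs[r, 1]]) / 2
      }, numeric(1)))
    }
    stat_for <- function(g) {
      ia <- which(g == focal)
      ib <- which(g != focal)
      w <- .pairs_within(ia)
      bt <- as.matrix(expand.grid(ia, ib))
      if (!is.null(subjects)) {
        bt <- bt[subjects[bt[, 1]] != subjects[bt[, 2]], , drop = FALSE]
        w <- w[subjects[w[, 1]] != subjects[w[, 2]], , drop = FALSE]
      }
      if (nrow(w) == 0 || nrow(bt) == 0) return(NA_real_)
      pair_mean(w) - pair_mean(bt)
    }
    observed <- stat_for(groups)
    null_stats <- numeric(B)
    for (b in seq_len(B)) {
      null_stats[b] <- stat_for(sample(groups))
    }
    null_stats <- null_stats[!is.na(null_stats)]
    p <- (1 + sum(null_stats >= observed)) / (length(null_stats) + 1)
    w_obs <- pair_mean(within)
    b_obs <- pair_mean(between)
    res <- list(observed_stat = observed, null_stats = null_stats,
                p_value = p, within_mean = w_obs, within_sd = NA_real_,
                between_mean = b_obs, between_sd = NA_real_)
  }
  structure(c(res, list(scheme = scheme, B = B, n_sampled = n_sampled,
                        seed = seed)), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result (%s, B = %d, %d contigs/draw): p = %.4g\n",
    x$scheme, x$B, x$n_sampled, x$p_value))
  cat(sprintf("  within:  %.2f%% +/- %s\n", 100 * x$within_mean,
              if (is.na(x$within_sd)) "NA"
              else sprintf("%.2f%%", 100 * x$within_sd)))
  cat(sprintf("  between: %.2f%% +/- %s\n", 100 * x$between_mean,
              if (is.na(x$between_sd)) "NA"
              else sprintf("%.2f%%", 100 * x$between_sd)))
  invisible(x)
}

#' Membership matrix of global assemblies
#'
#' Pools labeled contigs from several samples (for example time points of
#' one donor), assembles them into global assemblies at the standard
#' identity/overlap thresholds, and reports which samples contributed
#' contigs to each assembly, together with the percentage of assemblies
#' containing each sample: a persistence summary of the community.
#'
#' @param contigs named character vector of pooled contig sequences.
#' @param labels sample label per contig (same length/order).
#' @param include_singletons also count unmerged single contigs as
#'   assemblies (default `FALSE`: only multi-contig assemblies are
#'   persistence-informative).
#' @param min_identity,min_overlap_frac,min_overlap_abs assembly thresholds
#'   (defaults 0.98 / 0.50 / 25).
#' @return a `membership_matrix`: a logical matrix (assemblies x samples)
#'   with attribute `percentages` (named: 100 x fraction of assemblies
#'   containing each sample) and `assembly`, the underlying
#'   `assembly_result`.
#' @export
assembly_membership_matrix <- function(contigs, labels,
                                       include_singletons = FALSE,
                                       min_identity = 0.98,
                                       min_overlap_frac = 0.50,
                                       min_overlap_abs = 25) {
  contigs <- .as_seqset(contigs, "contigs")
  if (length(labels) != length(contigs) || anyNA(labels)) {
    stop("every pooled contig must carry a sample label")
  }
  labels <- as.character(labels)
  lab <- setNames(labels, names(contigs))
  asm <- assemble(contigs, min_identity = min_identity,
                  min_overlap_frac = min_overlap_frac,
                  min_overlap_abs = min_overlap_abs,
                  min_contig_len = 1)
  groups <- asm$members
  if (include_singletons && nrow(asm$singletons) > 0) {
    singles <- lapply(asm$singletons$read_id, identity)
    names(singles) <- asm$singletons$read_id
    groups <- c(groups, singles)
  }
  if (length(groups) == 0) {
    stop("no assemblies formed; nothing to summarize")
  }
  ulab <- sort(unique(labels))
  m <- t(vapply(groups, function(mem) {
    ulab %in% lab[mem]
  }, logical(length(ulab))))
  colnames(m) <- ulab
  pct <- 100 * colMeans(m)
  structure(m, percentages = pct, assembly = asm,
            class = c("membership_matrix", class(m)))
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between per-sample
#' abundance profiles over a shared feature space; bounded in `[0, 1]` for
#' non-negative input. Computed with [vegan::vegdist()]. Cells where both
#' profiles are all-zero are undefined and returned as `NA` with a
#' warning.
#'
#' @param profiles numeric matrix or data.frame, samples in rows, features
#'   in columns; non-negative.
#' @return a symmetric matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(profiles) {
  m <- as.matrix(profiles)
  if (any(m < 0)) stop("profiles must be non-negative")
  zero <- rowSums(m) == 0
  d <- suppressWarnings(as.matrix(vegan::vegdist(m, method = "bray")))
  if (any(zero)) {
    warning("all-zero profiles produce undefined distances (set to NA)")
    d[zero, zero] <- NA_real_
    diag(d) <- 0
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Embeds a distance matrix into Euclidean coordinates by
#' double-centering `-D^2/2` and eigendecomposition. Coordinates are built
#' from the top `k` non-negative eigenvalues; negative eigenvalues (which
#' arise for non-Euclidean distances such as Bray-Curtis) are reported, not
#' silently dropped.
#'
#' @param d symmetric distance matrix with zero diagonal (or a `dist`).
#' @param k number of dimensions (default 2; truncated to the number of
#'   positive eigenvalues, padded with zero coordinates if fewer).
#' @return a `pcoa_result`: a list with `points` (samples x k),
#'   `eigenvalues` (all, decreasing), `negative_fraction` (sum of absolute
#'   negative eigenvalues over sum of absolute eigenvalues) and
#'   `proportion_explained` over positive eigenvalues.
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8, na.rm = TRUE) ||
      any(abs(diag(d)) > 1e-12)) {
    stop("d must be a symmetric distance matrix with zero diagonal")
  }
  if (anyNA(d)) stop("d contains undefined distances")
  n <- nrow(d)
  if (k < 1) stop("k must be >= 1")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d * d) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values[1], 0) * 1e-12)
  kk <- min(k, length(pos))
  pts <- matrix(0, n, k)
  if (kk > 0) {
    pts[, seq_len(kk)] <- eig$vectors[, pos[seq_len(kk)], drop = FALSE] %*%
      diag(sqrt(eig$values[pos[seq_len(kk)]]), kk)
  }
  rownames(pts) <- rownames(d)
  neg <- eig$values[eig$values < 0]
  structure(list(
    points = pts, eigenvalues = eig$values,
    negative_fraction = sum(abs(neg)) / sum(abs(eig$values)),
    proportion_explained =
      if (length(pos) > 0) eig$values[pos] / sum(eig$values[pos])
      else numeric(0)),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf(
    "pcoa_result: %d samples, %d positive eigenvalues, negative fraction %.3g\n",
    nrow(x$points), length(x$proportion_explained), x$negative_fraction))
  invisible(x)
}
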