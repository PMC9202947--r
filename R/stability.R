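# Five reference-gene stability estimators plus geNorm's pairwise-variation
# criterion. All operate on a collapsed gene x sample Ct matrix restricted
# to one template kind; relative quantities are Q[g,s] = B^(min_s Ct - Ct)
# with base B = 2 by default or 1 + E/100 when per-gene efficiencies are
# supplied.

# log2 relative quantity matrix; efficiencies are percent (100 = doubling)
log2_quantity <- function(mat, efficiencies = NULL) {
  base <- gene_bases(rownames(mat), efficiencies)
  lq <- -(mat - apply(mat, 1, min)) * log2(base)
  dimnames(lq) <- dimnames(mat)
  lq
}

gene_bases <- function(genes, efficiencies = NULL) {
  if (is.null(efficiencies)) return(stats::setNames(rep(2, length(genes)),
                                                    genes))
  if (is.null(names(efficiencies))) {
    stop("`efficiencies` must be a named vector (gene -> percent)",
         call. = FALSE)
  }
  miss <- setdiff(genes, names(efficiencies))
  if (length(miss)) {
    stop("no efficiency supplied for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  e <- efficiencies[genes]
  if (any(!is.finite(e) | e <= 0)) {
    stop("efficiencies must be finite and > 0 (percent)", call. = FALSE)
  }
  1 + e / 100
}

sample_sd <- function(v) stats::sd(v)

new_stability_result <- function(method, scores, ranking = NULL,
                                 meta = list()) {
  if (is.null(ranking)) {
    ranking <- names(scores)[order(scores, names(scores))]
  }
  stopifnot(setequal(ranking, names(scores)))
  structure(list(method = method, scores = scores, ranking = ranking,
                 meta = meta),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability [", x$method, "]\n", sep = "")
  ord <- x$scores[x$ranking]
  print(round(ord, 4))
  if (!is.null(x$meta$best_pair)) {
    cat("best pair:", paste(x$meta$best_pair, collapse = "/"), "\n")
  }
  if (!is.null(x$meta$final_pair)) {
    cat("final pair:", paste(x$meta$final_pair, collapse = "/"),
        sprintf("(M = %.3f)\n", x$meta$pair_m))
  }
  invisible(x)
}

#' Convert a stability result to a data frame
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return Data frame with `gene`, `score`, `rank` and any per-gene
#'   method-specific columns.
#' @export
as.data.frame.stability_result <- function(x, ...) {
  genes <- x$ranking
  df <- data.frame(gene = genes, score = unname(x$scores[genes]),
                   rank = seq_along(genes), stringsAsFactors = FALSE)
  for (nm in intersect(names(x$meta), c("cv_pct", "accepted"))) {
    df[[nm]] <- unname(x$meta[[nm]][genes])
  }
  df
}

check_matrix <- function(mat, min_genes = 1, min_samples = 2, method) {
  if (nrow(mat) < min_genes) {
    stop(method, " requires at least ", min_genes, " genes", call. = FALSE)
  }
  if (ncol(mat) < min_samples) {
    stop(method, " requires at least ", min_samples, " samples",
         call. = FALSE)
  }
  invisible(mat)
}

#' BestKeeper-style stability from raw Ct dispersion
#'
#' Scores each gene by the dispersion of its per-sample mean Ct: the lower
#' the SD, the more stable the gene. Genes with SD <= `sd_accept` (default
#' 1 cycle) are flagged as acceptable reference genes. The percent CV
#' (100 * SD / mean Ct) is reported alongside.
#'
#' @param table A [ct_table] (one template kind; collapsed automatically).
#' @param dispersion `"sd"` (sample standard deviation, n-1 denominator;
#'   the default) or `"mad_geomean"` (mean absolute deviation around the
#'   geometric mean Ct, the original BestKeeper spreadsheet's estimator).
#' @param sd_accept Acceptance bound on the SD, in cycles.
#' @param template Optional template kind to select.
#' @return A `stability_result` with per-gene scores (cycles), ascending
#'   ranking, and `meta$cv_pct`, `meta$accepted`.
#' @export
bestkeeper <- function(table, dispersion = c("sd", "mad_geomean"),
                       sd_accept = 1, template = NULL) {
  dispersion <- match.arg(dispersion)
  mat <- as_ct_matrix(table, template)
  check_matrix(mat, 1, 2, "bestkeeper")
  disp <- switch(dispersion,
    sd = apply(mat, 1, sample_sd),
    mad_geomean = apply(mat, 1, function(v) mean(abs(v - exp(mean(log(v))))))
  )
  cv <- 100 * disp / rowMeans(mat)
  new_stability_result("bestkeeper", disp,
                       meta = list(cv_pct = cv, accepted = disp <= sd_accept,
                                   dispersion = dispersion))
}

#' Coefficient of variation of relative quantities
#'
#' Expression is rescaled per gene as Q[s] = B^(Ct_min - Ct[s]) (most
#' abundant sample has Q = 1); the score is the percent coefficient of
#' variation 100 * SD(Q) / mean(Q). Lower CV means higher stability.
#'
#' @inheritParams bestkeeper
#' @param efficiencies Optional named per-gene amplification efficiencies
#'   in percent; default base is 2 (perfect doubling).
#' @return A `stability_result` (scores in percent).
#' @export
cv_method <- function(table, efficiencies = NULL, template = NULL) {
  mat <- as_ct_matrix(table, template)
  check_matrix(mat, 1, 2, "cv_method")
  q <- 2^log2_quantity(mat, efficiencies)
  score <- 100 * apply(q, 1, sample_sd) / rowMeans(q)
  new_stability_result("cv", score)
}

#' Comparative delta-Ct stability
#'
#' For every pair of genes the per-sample Ct difference is formed and its
#' sample SD taken; a gene's score is the mean of these pair SDs over all
#' pairs that contain it. Genes that co-vary tightly with the rest of the
#' panel score low.
#'
#' @inheritParams bestkeeper
#' @return A `stability_result` (scores in cycles) with the full pair-SD
#'   matrix in `meta$pair_sd`.
#' @export
delta_ct_method <- function(table, template = NULL) {
  mat <- as_ct_matrix(table, template)
  check_matrix(mat, 3, 2, "delta_ct_method")
  genes <- rownames(mat)
  k <- length(genes)
  pair_sd <- matrix(0, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      s <- sample_sd(mat[i, ] - mat[j, ])
      pair_sd[i, j] <- pair_sd[j, i] <- s
    }
  }
  score <- rowSums(pair_sd) / (k - 1)
  new_stability_result("delta_ct", score, meta = list(pair_sd = pair_sd))
}

genorm_m_values <- function(lq) {
  genes <- rownames(lq)
  k <- length(genes)
  m <- stats::setNames(numeric(k), genes)
  for (i in seq_len(k)) {
    v <- vapply(seq_len(k)[-i],
                function(j) sample_sd(lq[i, ] - lq[j, ]), numeric(1))
    m[i] <- mean(v)
  }
  m
}

#' geNorm expression-stability analysis
#'
#' A gene's M value is the mean, over all other candidates, of the SD
#' across samples of the pairwise log2 expression ratio. The gene with the
#' largest M is removed and M values recomputed, iterating until two genes
#' remain; these form the best pair and share their mutual pairwise
#' variation as M. Genes with M above `m_threshold` (default 0.5) are
#' flagged as unsuitable references.
#'
#' Ties at the maximal M are broken by removing the lexicographically
#' later gene id, making the elimination deterministic.
#'
#' @inheritParams cv_method
#' @param m_threshold Flagging threshold on M.
#' @return A `stability_result`; scores are each gene's M at its round of
#'   elimination (the final pair shares its mutual V). `meta` records
#'   `elimination_order`, `m_by_round`, `final_pair`, `pair_m`,
#'   `unsuitable`. The ranking places the final pair (alphabetically) at
#'   positions 1-2, then the eliminated genes in reverse order of removal.
#' @export
genorm <- function(table, efficiencies = NULL, m_threshold = 0.5,
                   template = NULL) {
  mat <- as_ct_matrix(table, template)
  check_matrix(mat, 3, 2, "genorm")
  lq <- log2_quantity(mat, efficiencies)
  active <- rownames(lq)
  eliminated <- character(0)
  m_by_round <- list()
  score <- stats::setNames(numeric(nrow(lq)), rownames(lq))
  round_i <- 0L
  while (length(active) > 2) {
    round_i <- round_i + 1L
    m <- genorm_m_values(lq[active, , drop = FALSE])
    m_by_round[[round_i]] <- m
    worst_set <- names(m)[m == max(m)]
    worst <- max(worst_set)           # lexicographically later id on ties
    score[worst] <- m[worst]
    eliminated <- c(eliminated, worst)
    active <- setdiff(active, worst)
  }
  pair <- sort(active)
  pair_m <- sample_sd(lq[pair[1], ] - lq[pair[2], ])
  score[pair] <- pair_m
  m_by_round[[round_i + 1L]] <- stats::setNames(rep(pair_m, 2), pair)
  ranking <- c(pair, rev(eliminated))
  new_stability_result("genorm", score, ranking = ranking,
                       meta = list(elimination_order = eliminated,
                                   m_by_round = m_by_round,
                                   final_pair = pair, pair_m = pair_m,
                                   m_threshold = m_threshold,
                                   unsuitable = names(score)[score > m_threshold]))
}

#' geNorm pairwise variation V(n/n+1)
#'
#' For each n the normalization factor NF_n of a sample is the geometric
#' mean of the relative quantities of the n top-ranked genes; V(n/n+1) is
#' the SD across samples of log2(NF_n / NF_{n+1}). The recommended number
#' of reference genes is the smallest n with V(n/n+1) below `threshold`
#' (conventionally 0.15), or the full panel size if no V falls below it.
#'
#' @inheritParams genorm
#' @param ranking A gene ranking (best first); defaults to the [genorm()]
#'   ranking of `table`.
#' @param threshold Cut-off on V.
#' @return A `pairwise_variation` object: `v` (named numeric, `"V2/3"`,
#'   ...), `recommended`, `threshold`, `ranking`.
#' @export
genorm_pairwise_variation <- function(table, ranking = NULL, threshold = 0.15,
                                      efficiencies = NULL, template = NULL) {
  mat <- as_ct_matrix(table, template)
  check_matrix(mat, 3, 2, "genorm_pairwise_variation")
  if (is.null(ranking)) {
    ranking <- genorm(table, efficiencies = efficiencies,
                      template = template)$ranking
  }
  stopifnot(setequal(ranking, rownames(mat)))
  lq <- log2_quantity(mat, efficiencies)[ranking, , drop = FALSE]
  k <- nrow(lq)
  ns <- 2:(k - 1)
  v <- vapply(ns, function(n) {
    nf_n <- colMeans(lq[seq_len(n), , drop = FALSE])       # log2 NF_n
    nf_n1 <- colMeans(lq[seq_len(n + 1), , drop = FALSE])
    sample_sd(nf_n - nf_n1)
  }, numeric(1))
  names(v) <- sprintf("V%d/%d", ns, ns + 1)
  below <- ns[v < threshold]
  recommended <- if (length(below)) min(below) else k
  structure(list(v = v, recommended = recommended, threshold = threshold,
                 ranking = ranking),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat("geNorm pairwise variation (threshold ", x$threshold, "):\n", sep = "")
  print(round(x$v, 4))
  cat("recommended number of reference genes:", x$recommended, "\n")
  invisible(x)
}

# Intragroup variance estimator: two-way residuals within a group, with
# the cross-gene correction that makes the estimator unbiased under the
# common-sample-effect model; negative estimates truncated at 0.
normfinder_group_var <- function(y) {
  k <- nrow(y); n <- ncol(y)
  r <- y - rowMeans(y) - rep(colMeans(y), each = k) + mean(y)
  s <- rowSums(r^2) / (n - 1)
  pmax(0, (s - mean(s) / (k - 1)) * k / (k - 2))
}

#' NormFinder-style model-based stability
#'
#' Decomposes log-scale expression into intergroup and intragroup
#' variation under a two-group design. Per gene i and group g the
#' intergroup difference d\[i,g\] is the gene x group interaction of the
#' group means (constrained to sum to zero over genes within each group
#' and over groups within each gene), and the intragroup variance
#' sigma2\[i,g\] is the residual variance after removing gene and sample
#' effects within the group (bias-corrected, truncated at 0). The
#' differences are shrunk towards zero by an empirical-Bayes factor
#' gamma2 / (gamma2 + var(d-hat)), where gamma2 is a moment estimate of
#' the variance of the true intergroup differences, and the stability
#' value of a gene is the absolute shrunk difference plus the posterior SD
#' of the difference, averaged over the two groups. Lower is more stable.
#' The best two-gene combination minimizes the same criterion applied to
#' the average of the two genes' log expression.
#'
#' @inheritParams cv_method
#' @return A `stability_result`; `meta` records the `d` and `sigma2`
#'   matrices (genes x groups), `var_d`, `gamma2`, `best_pair` and
#'   `pair_stability`.
#' @export
normfinder <- function(table, efficiencies = NULL, template = NULL) {
  mat <- as_ct_matrix(table, template)
  check_matrix(mat, 3, 2, "normfinder")
  groups <- attr(mat, "groups")
  glab <- sort(unique(groups))
  if (length(glab) != 2) {
    stop("normfinder requires exactly 2 groups, got ",
         length(glab), " (", paste(glab, collapse = ", "), ")", call. = FALSE)
  }
  n_g <- table(factor(groups, levels = glab))
  if (any(n_g < 2)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  y <- log2_quantity(mat, efficiencies)
  k <- nrow(y); G <- 2L
  genes <- rownames(y)

  ybar <- sapply(glab, function(g) rowMeans(y[, groups == g, drop = FALSE]))
  sigma2 <- sapply(glab, function(g)
    normfinder_group_var(y[, groups == g, drop = FALSE]))
  dimnames(ybar) <- dimnames(sigma2) <- list(genes, glab)

  d <- ybar - rowMeans(ybar) -
    rep(colMeans(ybar), each = k) + mean(ybar)
  # sampling variance of the difference estimate: sigma^2/n per gene/group
  var_d <- sweep(sigma2, 2, as.numeric(n_g), "/")
  gamma2 <- max(0, (sum(d^2) - sum(var_d)) / ((k - 1) * (G - 1)))

  if (gamma2 == 0) {
    # no detectable intergroup variation: the posterior on every d is a
    # point mass at 0 and the criterion degenerates; rank by the
    # remaining source of normalization error, the sampling SD of the
    # gene's group means (intragroup variance only)
    sem2 <- sweep(sigma2, 2, as.numeric(n_g), "/")
    rho <- stats::setNames(rowMeans(sqrt(sem2)), genes)
    rho_ig <- sqrt(sem2)
    d_shrunk <- d * 0
  } else {
    shrink <- gamma2 / (gamma2 + var_d)
    d_shrunk <- d * shrink
    rho_ig <- abs(d_shrunk) + sqrt(var_d * shrink)
    rho <- stats::setNames(rowMeans(rho_ig), genes)
  }

  pair_score <- function(i, j) {
    dp <- (d[i, ] + d[j, ]) / 2
    vp <- (var_d[i, ] + var_d[j, ]) / 4
    if (gamma2 == 0) {
      return(mean(sqrt((sigma2[i, ] + sigma2[j, ]) / 4 / as.numeric(n_g))))
    }
    wp <- gamma2 / (gamma2 + vp)
    mean(abs(dp * wp) + sqrt(vp * wp))
  }
  pairs <- utils::combn(sort(genes), 2)
  pscores <- apply(pairs, 2, function(p) pair_score(p[1], p[2]))
  best <- pairs[, which.min(pscores)]

  new_stability_result("normfinder", rho,
                       meta = list(d = d, sigma2 = sigma2, var_d = var_d,
                                   gamma2 = gamma2,
                                   best_pair = best,
                                   pair_stability = min(pscores),
                                   groups = glab))
}

#' Run all five stability estimators
#'
#' @inheritParams cv_method
#' @param methods Which estimators to run.
#' @return A named list of `stability_result`s (NormFinder included only
#'   when the table carries exactly two groups).
#' @export
stability_all <- function(table, efficiencies = NULL, template = NULL,
                          methods = c("bestkeeper", "cv", "delta_ct",
                                      "genorm", "normfinder")) {
  methods <- match.arg(methods, several.ok = TRUE)
  res <- list()
  if ("bestkeeper" %in% methods) {
    res$bestkeeper <- bestkeeper(table, template = template)
  }
  if ("cv" %in% methods) {
    res$cv <- cv_method(table, efficiencies, template)
  }
  if ("delta_ct" %in% methods) {
    res$delta_ct <- delta_ct_method(table, template)
  }
  if ("genorm" %in% methods) {
    res$genorm <- genorm(table, efficiencies, template = template)
  }
  if ("normfinder" %in% methods) {
    res$normfinder <- normfinder(table, efficiencies, template)
  }
  res
}
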