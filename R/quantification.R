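#' Relative quantification by the 2^-ddCt method
#'
#' Normalizes a gene of interest to one or more reference genes and
#' expresses each sample relative to a calibrator group. Per sample,
#' `dCt = Ct_goi - mean(Ct_refs)` (the arithmetic mean of the normalizers'
#' Ct equals the geometric mean of their quantities);
#' `ddCt = dCt - mean(dCt over calibrator samples)`; the per-sample fold is
#' `2^-ddCt` and the group-level fold is `2^-(group mean ddCt)`, i.e. a
#' geometric-style mean. When per-gene efficiencies are supplied the same
#' calculation is carried out on the efficiency-corrected log2-quantity
#' scale (Pfaffl-style ratio); by default every gene amplifies with base 2.
#'
#' @param table A [ct_table] (one template kind; collapsed automatically).
#' @param goi Gene of interest id.
#' @param refs Character vector of one or more reference gene ids (must
#'   not include `goi`).
#' @param calibrator Group label whose mean dCt defines fold 1.
#' @param efficiencies Optional named per-gene efficiencies in percent.
#' @param template Optional template kind to select.
#' @param var_equal Use the pooled-variance t-test (default); `FALSE` for
#'   Welch.
#' @return A `rel_expr_result`: `samples` (per-sample `delta_ct` in cycles,
#'   `delta` on the log2-quantity scale, `ddct`, `fold`), `groups`
#'   (per-group mean/SD of dCt, fold and a dispersion band), `test`
#'   (two-tailed t-test on per-sample delta values between groups).
#' @export
ddct <- function(table, goi, refs, calibrator, efficiencies = NULL,
                 template = NULL, var_equal = TRUE) {
  mat <- as_ct_matrix(table, template)
  if (goi %in% refs) {
    stop("gene of interest '", goi, "' cannot be one of the reference genes",
         call. = FALSE)
  }
  miss <- setdiff(c(goi, refs), rownames(mat))
  if (length(miss)) {
    stop("gene(s) not present in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  groups <- attr(mat, "groups")
  calibrator <- normalize_group(calibrator)
  if (!calibrator %in% groups) {
    stop("calibrator group '", calibrator, "' not found; groups are: ",
         paste(unique(groups), collapse = ", "), call. = FALSE)
  }
  base <- gene_bases(rownames(mat), efficiencies)
  y <- -mat * log2(base)                 # log2 quantity up to per-gene const
  delta <- y[goi, ] - colMeans(y[refs, , drop = FALSE])
  delta_ct <- mat[goi, ] - colMeans(mat[refs, , drop = FALSE])
  cal <- groups == calibrator
  dd <- delta - mean(delta[cal])         # = -ddCt when base is 2
  fold <- 2^dd

  samples <- data.frame(sample = colnames(mat), group = unname(groups),
                        delta_ct = unname(delta_ct), delta = unname(delta),
                        ddct = -unname(dd), fold = unname(fold),
                        stringsAsFactors = FALSE)
  grp <- do.call(rbind, lapply(split(samples, samples$group), function(d) {
    m <- mean(-d$ddct); s <- stats::sd(-d$ddct)
    data.frame(group = d$group[1], n = nrow(d),
               mean_delta_ct = mean(d$delta_ct),
               sd_delta_ct = stats::sd(d$delta_ct),
               fold = 2^m, fold_lo = 2^(m - s), fold_hi = 2^(m + s),
               stringsAsFactors = FALSE)
  }))
  rownames(grp) <- NULL
  res <- structure(list(goi = goi, refs = refs, calibrator = calibrator,
                        efficiencies = efficiencies,
                        samples = samples, groups = grp, test = NULL),
                   class = "rel_expr_result")
  res$test <- compare_groups(res, var_equal = var_equal)
  res
}

#' Compare groups on the normalized expression scale
#'
#' Two-tailed unpaired t-test on the per-sample dCt values (log scale;
#' with efficiency correction, the corresponding log2-quantity
#' differences) between the two groups of a [ddct()] result. Pooled
#' variance by default, Welch with `var_equal = FALSE`.
#'
#' @param result A `rel_expr_result`.
#' @param var_equal Pooled (default) or Welch.
#' @param on `"delta_ct"` (default) to test dCt values, `"fold"` to test
#'   the per-sample fold changes instead.
#' @return A list with `statistic` (t), `df`, `p_value`, `method`.
#' @export
compare_groups <- function(result, var_equal = TRUE, on = c("delta_ct",
                                                            "fold")) {
  stopifnot(inherits(result, "rel_expr_result"))
  on <- match.arg(on)
  s <- result$samples
  glab <- unique(s$group)
  if (length(glab) != 2) {
    stop("group comparison requires exactly 2 groups", call. = FALSE)
  }
  sizes <- table(s$group)
  if (any(sizes < 2)) {
    stop("each group needs at least 2 samples for a t-test", call. = FALSE)
  }
  v <- if (on == "delta_ct") s$delta else s$fold
  a <- v[s$group == glab[1]]
  b <- v[s$group == glab[2]]
  if (isTRUE(all.equal(stats::sd(a) + stats::sd(b), 0))) {
    # zero within-group variance (e.g. noise-free simulated data): the
    # t statistic degenerates to 0 (equal means) or +/-Inf
    df <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = df, p_value = 1,
                  method = "Two Sample t-test (zero variance)"))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, df = df,
                p_value = 0, method = "Two Sample t-test (zero variance)"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = tt$method)
}

#' @export
print.rel_expr_result <- function(x, ...) {
  cat("Relative expression of ", x$goi, " normalized to ",
      paste(x$refs, collapse = "/"), " (calibrator: ", x$calibrator, ")\n",
      sep = "")
  print(x$groups, digits = 4)
  cat(sprintf("t = %.4f, df = %.4g, p = %.4g\n", x$test$statistic,
              x$test$df, x$test$p_value))
  invisible(x)
}

#' Serialize a relative-expression result
#' @param x A `rel_expr_result`.
#' @param csv,json Optional output paths (CSV: per-sample table).
#' @return Invisibly, `x`.
#' @export
write_rel_expr <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "rel_expr_result"))
  if (!is.null(csv)) utils::write.csv(x$samples, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(goi = x$goi, refs = x$refs,
                              calibrator = x$calibrator,
                              samples = x$samples, groups = x$groups,
                              test = x$test),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
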