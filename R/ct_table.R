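#' @keywords internal
CT_COLUMNS <- c("gene", "sample", "group", "template", "replicate", "ct")

normalize_group <- function(x) tolower(trimws(as.character(x)))

normalize_template <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("polya", "poly(a)", "poly-a", "mrna")] <- "polyA"
  x[x %in% c("total", "total rna", "totalrna")] <- "total"
  x
}

#' Construct a validated Ct table
#'
#' A Ct table holds quantification-cycle values for a set of genes measured
#' in a set of samples, each sample carrying a group label (e.g. `"egg"` /
#' `"cortex"`), a template kind (`"total"` or `"polyA"`) and one or more
#' technical replicates per gene x sample cell. It is the central input of
#' every stability estimator and of the relative-quantification routines.
#'
#' @param data A data frame with columns `gene`, `sample`, `group`,
#'   `template`, `replicate` and `ct` (one row per technical replicate).
#' @return An object of class `ct_table` (a data frame with the six
#'   canonical columns, labels normalized to canonical case).
#' @details Every Ct value must be finite and strictly positive; group
#'   labels are free strings (lower-cased), so the pipeline generalizes to
#'   any two-group design. Template kinds are canonicalized to `"total"` /
#'   `"polyA"` when recognized. A sample must carry a single group and
#'   template label.
#' @examples
#' df <- expand.grid(gene = c("Ubb", "28S"), sample = paste0("s", 1:2),
#'                   replicate = 1:2)
#' df$group <- ifelse(df$sample == "s1", "egg", "cortex")
#' df$template <- "total"
#' df$ct <- 20 + rnorm(nrow(df), sd = 0.1)
#' ct_table(df)
#' @export
ct_table <- function(data) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(CT_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(data)[CT_COLUMNS]
  df$gene <- as.character(df$gene)
  df$sample <- as.character(df$sample)
  df$group <- normalize_group(df$group)
  df$template <- normalize_template(df$template)
  df$replicate <- as.integer(df$replicate)
  ct <- suppressWarnings(as.numeric(as.character(df$ct)))
  bad <- which(!is.finite(ct) | ct <= 0)
  if (length(bad)) {
    stop("non-numeric or non-positive Ct value(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  df$ct <- ct
  meta <- unique(df[c("sample", "group", "template")])
  dup <- meta$sample[duplicated(meta$sample)]
  if (length(dup)) {
    stop("sample(s) with conflicting group/template labels: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a Ct table from CSV
#'
#' @param path Path to a CSV file.
#' @param layout `"long"` (columns `gene`, `sample`, `group`, `template`,
#'   `replicate`, `ct`) or `"wide"` (columns `gene`, `replicate`, then one
#'   column per sample holding Ct values).
#' @param sample_info For the wide layout, a data frame with columns
#'   `sample`, `group`, `template` mapping sample columns to their labels.
#' @return A [ct_table].
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), sample_info = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "long") return(ct_table(raw))
  need <- setdiff(c("gene", "replicate"), names(raw))
  if (length(need)) {
    stop("missing required column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(sample_info)) {
    stop("wide layout requires `sample_info` (sample, group, template)",
         call. = FALSE)
  }
  need <- setdiff(c("sample", "group", "template"), names(sample_info))
  if (length(need)) {
    stop("`sample_info` is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), c("gene", "replicate"))
  unknown <- setdiff(sample_cols, sample_info$sample)
  if (length(unknown)) {
    stop("sample column(s) absent from `sample_info`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  long <- do.call(rbind, lapply(sample_cols, function(s) {
    data.frame(gene = raw$gene, sample = s,
               group = sample_info$group[match(s, sample_info$sample)],
               template = sample_info$template[match(s, sample_info$sample)],
               replicate = raw$replicate, ct = raw[[s]],
               stringsAsFactors = FALSE)
  }))
  ct_table(long)
}

#' Write a Ct table to CSV
#'
#' The long layout round-trips value-exactly through [read_ct_table()].
#'
#' @param x A [ct_table].
#' @param path Output path.
#' @param layout `"long"` or `"wide"`.
#' @return Invisibly, `path`.
#' @export
write_ct_table <- function(x, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "ct_table"))
  if (layout == "long") {
    out <- as.data.frame(x)
    out$ct <- sprintf("%.17g", out$ct)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    samples <- unique(x$sample)
    key <- unique(x[c("gene", "replicate")])
    wide <- key
    for (s in samples) {
      sub <- x[x$sample == s, ]
      wide[[s]] <- sub$ct[match(paste(key$gene, key$replicate),
                                paste(sub$gene, sub$replicate))]
    }
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Collapse technical replicates to per-sample mean Ct
#'
#' Each gene x sample cell is replaced by the arithmetic mean of its
#' technical replicates (on the Ct scale). A QC report records, per cell,
#' the replicate spread (max - min, cycles) and a pass flag; cells with
#' spread at or above `max_spread` are flagged but retained, never dropped.
#' Collapsing is idempotent.
#'
#' @param x A [ct_table].
#' @param max_spread QC threshold on replicate spread, in cycles. Default
#'   0.5, the conventional bound below which technical triplicates are
#'   considered concordant.
#' @return A collapsed `ct_table` (one value per cell, `replicate = 1`)
#'   carrying the QC report as attribute `"qc"`; retrieve it with
#'   [qc_report()].
#' @export
collapse_replicates <- function(x, max_spread = 0.5) {
  stopifnot(inherits(x, "ct_table"))
  if (!is.numeric(max_spread) || max_spread <= 0) {
    stop("`max_spread` must be a positive number of cycles", call. = FALSE)
  }
  keys <- c("gene", "sample", "group", "template")
  agg <- stats::aggregate(ct ~ gene + sample + group + template, data = x,
                          FUN = function(v) c(mean = mean(v),
                                              spread = max(v) - min(v),
                                              n = length(v)))
  cells <- data.frame(agg[keys],
                      n_replicates = as.integer(agg$ct[, "n"]),
                      mean_ct = agg$ct[, "mean"],
                      spread = agg$ct[, "spread"],
                      stringsAsFactors = FALSE)
  cells$pass <- cells$spread < max_spread
  cells <- cells[order(cells$gene, cells$sample), ]
  rownames(cells) <- NULL

  out <- ct_table(data.frame(gene = cells$gene, sample = cells$sample,
                             group = cells$group, template = cells$template,
                             replicate = 1L, ct = cells$mean_ct,
                             stringsAsFactors = FALSE))
  gene_sum <- do.call(rbind, lapply(split(cells, cells[c("gene", "template")],
                                          drop = TRUE), function(d) {
    data.frame(gene = d$gene[1], template = d$template[1],
               mean_ct = mean(d$mean_ct), min_ct = min(d$mean_ct),
               max_ct = max(d$mean_ct),
               range = max(d$mean_ct) - min(d$mean_ct),
               stringsAsFactors = FALSE)
  }))
  rownames(gene_sum) <- NULL
  qc <- structure(list(cells = cells, genes = gene_sum,
                       max_spread = max_spread,
                       n_flagged = sum(!cells$pass)),
                  class = "qc_report")
  attr(out, "qc") <- qc
  out
}

#' Retrieve the QC report attached by [collapse_replicates()]
#' @param x A collapsed [ct_table].
#' @return A `qc_report` object (lists `cells`, `genes`, `max_spread`,
#'   `n_flagged`), or `NULL` if none is attached.
#' @export
qc_report <- function(x) attr(x, "qc")

#' @export
print.qc_report <- function(x, ...) {
  cat("Ct replicate QC: ", nrow(x$cells), " cells, ",
      x$n_flagged, " flagged (spread >= ", x$max_spread, " cycles)\n",
      sep = "")
  invisible(x)
}

#' Serialize a QC report
#'
#' @param qc A `qc_report`.
#' @param csv,json Optional output paths; the CSV holds the per-cell table,
#'   the JSON the full report.
#' @return Invisibly, the report.
#' @export
write_qc_report <- function(qc, csv = NULL, json = NULL) {
  stopifnot(inherits(qc, "qc_report"))
  if (!is.null(csv)) utils::write.csv(qc$cells, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(cells = qc$cells, genes = qc$genes,
                              max_spread = qc$max_spread,
                              n_flagged = qc$n_flagged),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(qc)
}

#' Per-gene Ct summary
#'
#' Summarizes per-sample mean Ct per gene (and template kind): mean,
#' minimum, maximum and range (max - min) across samples. The output is
#' ordered by ascending mean Ct within each template kind, i.e. most
#' abundant transcript first.
#'
#' @param x A [ct_table]; collapsed automatically if it still carries
#'   technical replicates.
#' @return A data frame with columns `template`, `gene`, `mean_ct`,
#'   `min_ct`, `max_ct`, `range`, `n_samples`.
#' @export
summarize_ct <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  x <- if (needs_collapse(x)) collapse_replicates(x) else x
  out <- do.call(rbind, lapply(split(as.data.frame(x),
                                     x[c("gene", "template")], drop = TRUE),
                               function(d) {
    if (nrow(d) < 2) {
      stop("gene ", d$gene[1], " (", d$template[1], "): fewer than 2 samples;",
           " Ct range is undefined", call. = FALSE)
    }
    data.frame(template = d$template[1], gene = d$gene[1],
               mean_ct = mean(d$ct), min_ct = min(d$ct), max_ct = max(d$ct),
               range = max(d$ct) - min(d$ct), n_samples = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$template, out$mean_ct), ]
  rownames(out) <- NULL
  out
}

needs_collapse <- function(x) {
  anyDuplicated(paste(x$gene, x$sample)) > 0
}

#' Ct table as a gene x sample matrix
#'
#' Restricts the table to one template kind, collapses technical replicates
#' if present, and returns the complete gene x sample matrix the stability
#' and quantification methods operate on. Missing gene x sample cells are
#' an error: the estimators assume a complete matrix and nothing is
#' imputed.
#'
#' @param x A [ct_table].
#' @param template Template kind to select; may be omitted when the table
#'   holds a single kind.
#' @return A numeric matrix (genes x samples) with attribute `"groups"`, a
#'   named character vector mapping sample to group label.
#' @export
as_ct_matrix <- function(x, template = NULL) {
  stopifnot(inherits(x, "ct_table"))
  if (!is.null(template)) {
    template <- normalize_template(template)
    x <- x[x$template == template, ]
    if (!nrow(x)) stop("no samples with template kind '", template, "'",
                       call. = FALSE)
    x <- ct_table(as.data.frame(x))
  }
  kinds <- unique(x$template)
  if (length(kinds) > 1) {
    stop("table holds several template kinds (",
         paste(kinds, collapse = ", "),
         "); select one with `template =`", call. = FALSE)
  }
  if (needs_collapse(x)) x <- collapse_replicates(x)
  genes <- sort(unique(x$gene))
  samples <- unique(x$sample)
  mat <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  mat[cbind(match(x$gene, genes), match(x$sample, samples))] <- x$ct
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    stop("missing gene x sample cell(s), e.g. ",
         genes[miss[1, 1]], " / ", samples[miss[1, 2]],
         "; stability analysis requires a complete matrix", call. = FALSE)
  }
  groups <- x$group[match(samples, x$sample)]
  names(groups) <- samples
  attr(mat, "groups") <- groups
  mat
}

#' @export
print.ct_table <- function(x, ...) {
  cat("Ct table: ", length(unique(x$gene)), " genes x ",
      length(unique(x$sample)), " samples (",
      nrow(x), " measurements; template: ",
      paste(unique(x$template), collapse = ", "), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
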