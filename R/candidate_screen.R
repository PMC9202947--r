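#' Construct an FPKM abundance table
#'
#' Transcript abundance (FPKM) in two conditions, used to screen for
#' reference-gene candidates (abundant, similar between conditions) and
#' for enriched genes of interest.
#'
#' @param transcript Transcript/gene identifiers.
#' @param fpkm_a,fpkm_b FPKM in condition A (e.g. whole eggs) and
#'   condition B (e.g. isolated cortices); must be >= 0.
#' @param conditions Length-2 character vector naming the conditions.
#' @return An `fpkm_table` (a data frame).
#' @export
fpkm_table <- function(transcript, fpkm_a, fpkm_b,
                       conditions = c("egg", "cortex")) {
  df <- data.frame(transcript = as.character(transcript),
                   fpkm_a = as.numeric(fpkm_a), fpkm_b = as.numeric(fpkm_b),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$fpkm_a) | df$fpkm_a < 0 |
          !is.finite(df$fpkm_b) | df$fpkm_b < 0)) {
    stop("FPKM values must be finite and >= 0", call. = FALSE)
  }
  attr(df, "conditions") <- conditions
  class(df) <- c("fpkm_table", "data.frame")
  df
}

#' Read an FPKM table from CSV/TSV
#'
#' Expects columns `transcript` (or `id`), then the two condition columns
#' (by default `fpkm_egg`, `fpkm_cortex`, or plain `egg`/`cortex`).
#'
#' @param path File path (comma- or tab-separated by extension).
#' @return An [fpkm_table].
#' @export
read_fpkm_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  id_col <- intersect(c("transcript", "id", "gene"), names(raw))[1]
  if (is.na(id_col)) stop("no transcript id column found", call. = FALSE)
  rest <- setdiff(names(raw), id_col)
  if (length(rest) < 2) {
    stop("two condition columns of FPKM values are required", call. = FALSE)
  }
  fpkm_table(raw[[id_col]], raw[[rest[1]]], raw[[rest[2]]],
             conditions = sub("^fpkm_", "", rest[1:2]))
}

#' Screen for reference-gene candidates
#'
#' Retains transcripts that are abundant in both conditions
#' (`min(FPKM) >= min_fpkm`) and similar between them
#' (`max(A/B, B/A) <= max_fold`), sorted by descending mean abundance.
#' The fold-change bound is an explicit, configurable proxy for a
#' replicate-level differential-expression call, whose inputs this table
#' does not carry.
#'
#' @param table An [fpkm_table].
#' @param min_fpkm Minimum FPKM required in both conditions (> 0).
#' @param max_fold Maximum between-condition fold change (>= 1).
#' @return The subset of `table` passing the screen, with columns
#'   `fold` (max ratio, >= 1) and `mean_fpkm`.
#' @export
screen_reference_candidates <- function(table, min_fpkm = 1000,
                                        max_fold = 1.5) {
  stopifnot(inherits(table, "fpkm_table"))
  if (!is.numeric(min_fpkm) || min_fpkm <= 0) {
    stop("`min_fpkm` must be > 0", call. = FALSE)
  }
  if (!is.numeric(max_fold) || max_fold < 1) {
    stop("`max_fold` must be >= 1", call. = FALSE)
  }
  df <- as.data.frame(table)
  keep <- pmin(df$fpkm_a, df$fpkm_b) >= min_fpkm
  df <- df[keep, , drop = FALSE]
  df$fold <- pmax(df$fpkm_a / df$fpkm_b, df$fpkm_b / df$fpkm_a)
  df <- df[df$fold <= max_fold, , drop = FALSE]
  df$mean_fpkm <- (df$fpkm_a + df$fpkm_b) / 2
  df <- df[order(-df$mean_fpkm, df$transcript), ]
  rownames(df) <- NULL
  df
}

#' Screen for enriched gene-of-interest candidates
#'
#' Retains transcripts detected in both conditions (`FPKM > min_fpkm`)
#' whose abundance in condition B is at least `min_fold` times that in
#' condition A, sorted by descending enrichment fold.
#'
#' @param table An [fpkm_table].
#' @param min_fpkm Detection threshold applied to both conditions (> 0).
#' @param min_fold Minimum B/A enrichment fold (> 0).
#' @return The subset of `table` passing the screen, with column `fold`
#'   (B/A).
#' @export
screen_goi_candidates <- function(table, min_fpkm = 0.5, min_fold = 2) {
  stopifnot(inherits(table, "fpkm_table"))
  if (!is.numeric(min_fpkm) || min_fpkm <= 0) {
    stop("`min_fpkm` must be > 0", call. = FALSE)
  }
  if (!is.numeric(min_fold) || min_fold <= 0) {
    stop("`min_fold` must be > 0", call. = FALSE)
  }
  df <- as.data.frame(table)
  keep <- df$fpkm_a > min_fpkm & df$fpkm_b > min_fpkm
  df <- df[keep, , drop = FALSE]
  df$fold <- df$fpkm_b / df$fpkm_a
  df <- df[df$fold >= min_fold, , drop = FALSE]
  df <- df[order(-df$fold, df$transcript), ]
  rownames(df) <- NULL
  df
}
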