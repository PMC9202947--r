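#' Aggregate per-method rankings into a consensus table
#'
#' Builds a methods x rank-position matrix (the geNorm best pair occupies
#' positions 1-2 jointly, rendered as `"A/B"`) and a consensus ordering.
#' The consensus score of a gene is the geometric mean of its per-method
#' ranks, with each member of a geNorm pair taking rank 1.5; the consensus
#' ordering sorts ascending score, ties broken alphabetically. The
#' consensus is this package's explicit formalization of an overall "most
#' suitable" call and is labeled as such in output.
#'
#' @param results A `stability_result` or list of them, all over the same
#'   gene set.
#' @return A `rank_table`: `positions` (character matrix, methods x
#'   positions), `ranks` (numeric matrix, genes x methods), `consensus`
#'   (data frame `gene`, `score`, `rank`).
#' @export
aggregate_rankings <- function(results) {
  if (inherits(results, "stability_result")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "stability_result")))
  gene_sets <- lapply(results, function(r) sort(names(r$scores)))
  if (length(unique(gene_sets)) != 1) {
    stop("stability results cover inconsistent gene sets", call. = FALSE)
  }
  genes <- gene_sets[[1]]
  k <- length(genes)
  methods <- vapply(results, `[[`, character(1), "method")
  if (anyDuplicated(methods)) {
    methods <- make.unique(methods)
  }

  ranks <- matrix(NA_real_, k, length(results),
                  dimnames = list(genes, methods))
  positions <- matrix("", length(results), k,
                      dimnames = list(methods, paste0("rank", seq_len(k))))
  for (m in seq_along(results)) {
    r <- results[[m]]
    pair <- r$meta$final_pair
    pos <- r$ranking
    if (!is.null(pair)) {
      ranks[pos, m] <- seq_len(k)
      ranks[pair, m] <- 1.5
      positions[m, 1] <- paste(pair, collapse = "/")
      positions[m, 2] <- ""
      if (k > 2) positions[m, 3:k] <- pos[3:k]
    } else {
      ranks[pos, m] <- seq_len(k)
      positions[m, ] <- pos
    }
  }
  score <- exp(rowMeans(log(ranks)))
  consensus <- data.frame(gene = genes, score = unname(score),
                          stringsAsFactors = FALSE)
  consensus <- consensus[order(consensus$score, consensus$gene), ]
  consensus$rank <- seq_len(k)
  rownames(consensus) <- NULL
  structure(list(positions = positions, ranks = ranks,
                 consensus = consensus),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("Stability ranking by method (best first):\n")
  print(as.data.frame(x$positions))
  cat("\nConsensus (geometric mean of ranks; package's formalization):\n")
  print(x$consensus)
  invisible(x)
}

#' Render a rank table
#' @param x A `rank_table`.
#' @param format `"markdown"` or `"csv"`.
#' @return A character vector of lines.
#' @export
format_rank_table <- function(x, format = c("markdown", "csv")) {
  format <- match.arg(format)
  pos <- x$positions
  if (format == "csv") {
    header <- paste(c("method", colnames(pos)), collapse = ",")
    rows <- vapply(rownames(pos), function(m)
      paste(c(m, pos[m, ]), collapse = ","), character(1))
    return(c(header, unname(rows)))
  }
  header <- paste0("| method | ", paste(seq_len(ncol(pos)), collapse = " | "),
                   " |")
  sep <- paste0("|", paste(rep("---", ncol(pos) + 1), collapse = "|"), "|")
  rows <- vapply(rownames(pos), function(m)
    paste0("| ", m, " | ", paste(pos[m, ], collapse = " | "), " |"),
    character(1))
  c(header, sep, unname(rows))
}

#' Serialize a rank table
#' @param x A `rank_table`.
#' @param csv,json Optional output paths.
#' @return Invisibly, `x`.
#' @export
write_rank_table <- function(x, csv = NULL, json = NULL) {
  if (!is.null(csv)) writeLines(format_rank_table(x, "csv"), csv)
  if (!is.null(json)) {
    jsonlite::write_json(list(positions = as.data.frame(x$positions),
                              consensus = x$consensus),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
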