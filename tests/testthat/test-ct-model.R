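make_long_df <- function(n_genes = 7, n_per_group = 3, n_rep = 3,
                         template = "total") {
  genes <- paste0("g", seq_len(n_genes))
  samples <- c(paste0("egg_", seq_len(n_per_group)),
               paste0("cortex_", seq_len(n_per_group)))
  df <- expand.grid(gene = genes, sample = samples, replicate = seq_len(n_rep),
                    stringsAsFactors = FALSE)
  df$group <- sub("_.*", "", df$sample)
  df$template <- template
  df$ct <- 20 + match(df$gene, genes) + 0.1 * df$replicate
  df
}

test_that("a 7-gene x 6-sample x 3-replicate design yields 126 values", {
  tab <- ct_table(make_long_df())
  expect_s3_class(tab, "ct_table")
  expect_equal(nrow(tab), 7 * 6 * 3)
  expect_equal(sort(unique(tab$group)), c("cortex", "egg"))
})

test_that("loader errors name the missing column and bad Ct rows", {
  df <- make_long_df()
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[setdiff(names(df), "ct")], f, row.names = FALSE)
  expect_error(read_ct_table(f), "ct")

  df_bad <- df
  df_bad$ct <- as.character(df_bad$ct)
  df_bad$ct[5] <- "n/a"
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df_bad, f2, row.names = FALSE)
  expect_error(read_ct_table(f2), "row")
  expect_error(read_ct_table(f2), "5")

  df_neg <- df
  df_neg$ct[3] <- -1
  expect_error(ct_table(df_neg), "non-positive")
})

test_that("write/read round trip is value-exact for long and wide layouts", {
  sim <- simulate_ct_experiment(preset_sea_urchin(), seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(sim$table, f, layout = "long")
  back <- read_ct_table(f, layout = "long")
  expect_identical(back$ct, sim$table$ct)
  expect_identical(back$gene, sim$table$gene)

  fw <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(sim$table, fw, layout = "wide")
  info <- unique(as.data.frame(sim$table)[c("sample", "group", "template")])
  back_w <- read_ct_table(fw, layout = "wide", sample_info = info)
  key <- function(d) d[order(d$gene, d$sample, d$replicate), ]
  expect_equal(key(as.data.frame(back_w))$ct,
               key(as.data.frame(sim$table))$ct)
})

test_that("labels are normalized and conflicting sample labels rejected", {
  df <- make_long_df(template = "mRNA")
  df$group <- toupper(df$group)
  tab <- ct_table(df)
  expect_equal(unique(tab$template), "polyA")
  expect_setequal(unique(tab$group), c("egg", "cortex"))

  df2 <- make_long_df()
  df2$group[1] <- "cortex"     # conflicts with egg_1's other rows
  expect_error(ct_table(df2), "conflicting")
})

test_that("replicate collapsing averages, flags wide spreads, keeps cells", {
  df <- data.frame(gene = "g1", sample = rep(c("a", "b"), each = 3),
                   group = rep(c("egg", "cortex"), each = 3),
                   template = "total", replicate = rep(1:3, 2),
                   ct = c(20.0, 20.0, 20.0, 20.0, 20.3, 20.6))
  col <- collapse_replicates(ct_table(df), max_spread = 0.5)
  qc <- qc_report(col)
  cells <- qc$cells[order(qc$cells$sample), ]
  expect_equal(cells$mean_ct, c(20.0, 20.3))
  expect_equal(cells$spread, c(0.0, 0.6))
  expect_equal(cells$pass, c(TRUE, FALSE))   # 0.6 flagged at threshold 0.5
  expect_equal(nrow(col), 2)                 # flagged cell retained
  expect_equal(qc$n_flagged, 1L)
})

test_that("collapsing is idempotent and spread boundary flags at >= max_spread", {
  sim <- simulate_ct_experiment(preset_sea_urchin(), seed = 7)
  once <- collapse_replicates(sim$table)
  twice <- collapse_replicates(once)
  expect_equal(as.data.frame(twice)[order(twice$gene, twice$sample), ]$ct,
               as.data.frame(once)[order(once$gene, once$sample), ]$ct)

  df <- data.frame(gene = "g", sample = rep(c("a", "b"), each = 2),
                   group = "egg", template = "total", replicate = rep(1:2, 2),
                   ct = c(20, 20.5, 20, 20.4))
  qc <- qc_report(collapse_replicates(ct_table(df), max_spread = 0.5))
  expect_equal(qc$cells$pass[order(qc$cells$sample)], c(FALSE, TRUE))
})

test_that("per-gene shift moves the mean, not spread or range", {
  sim <- simulate_ct_experiment(preset_sea_urchin(), seed = 11)
  df <- as.data.frame(sim$table)
  shifted <- df
  shifted$ct[shifted$gene == "Ubb"] <- shifted$ct[shifted$gene == "Ubb"] + 3

  s0 <- summarize_ct(collapse_replicates(sim$table))
  s1 <- summarize_ct(collapse_replicates(ct_table(shifted)))
  ubb0 <- s0[s0$gene == "Ubb", ]; ubb1 <- s1[s1$gene == "Ubb", ]
  expect_equal(ubb1$mean_ct, ubb0$mean_ct + 3)
  expect_equal(ubb1$range, ubb0$range)
  q0 <- qc_report(collapse_replicates(sim$table))$cells
  q1 <- qc_report(collapse_replicates(ct_table(shifted)))$cells
  expect_equal(q1$spread[q1$gene == "Ubb"], q0$spread[q0$gene == "Ubb"])
})

test_that("summarize_ct computes mean and range, ordered by abundance", {
  mat <- rbind(hi = c(10, 12, 14), lo = c(25, 25, 26))
  tab <- matrix_ct_table(mat)
  s <- summarize_ct(tab)
  expect_equal(s$gene, c("hi", "lo"))  # ascending mean Ct
  expect_equal(s$mean_ct[1], 12)
  expect_equal(s$range[1], 4)

  one <- matrix_ct_table(matrix(20, 1, 1, dimnames = list("g", "s")))
  expect_error(summarize_ct(one), "fewer than 2 samples")
})

test_that("as_ct_matrix enforces a single template and complete cells", {
  df_a <- make_long_df(2, 2, 1, "total")
  df_b <- make_long_df(2, 2, 1, "polyA")
  df_b$sample <- paste0("m_", df_b$sample)   # disjoint sample sets per kind
  tab <- ct_table(rbind(df_a, df_b))
  expect_error(as_ct_matrix(tab), "template")
  m <- as_ct_matrix(tab, template = "polyA")
  expect_equal(dim(m), c(2, 4))

  df_missing <- make_long_df(2, 2, 1)
  df_missing <- df_missing[-1, ]
  expect_error(as_ct_matrix(ct_table(df_missing)), "missing")
})
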