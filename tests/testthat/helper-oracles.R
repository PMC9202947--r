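# Independent, naive, loop-based implementations of the stability
# definitions. These deliberately share no code with the package: every
# quantity is computed from first principles with explicit loops, so they
# can serve as oracles for the optimized implementations.

naive_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

naive_bestkeeper <- function(mat) {
  sapply(rownames(mat), function(g) naive_sd(mat[g, ]))
}

naive_cv <- function(mat, base = 2) {
  sapply(rownames(mat), function(g) {
    q <- base^(min(mat[g, ]) - mat[g, ])
    100 * naive_sd(q) / mean(q)
  })
}

naive_delta_ct <- function(mat) {
  genes <- rownames(mat)
  sapply(genes, function(g) {
    others <- setdiff(genes, g)
    mean(sapply(others, function(h) naive_sd(mat[g, ] - mat[h, ])))
  })
}

naive_genorm_m <- function(mat, base = 2) {
  lq <- t(sapply(rownames(mat), function(g)
    log2(base^(min(mat[g, ]) - mat[g, ]))))
  genes <- rownames(mat)
  sapply(genes, function(g) {
    others <- setdiff(genes, g)
    mean(sapply(others, function(h) naive_sd(lq[g, ] - lq[h, ])))
  })
}

# full stepwise elimination; returns list(elimination, final_pair, m_at_exit)
naive_genorm <- function(mat) {
  active <- rownames(mat)
  elim <- character(0)
  m_at_exit <- numeric(0)
  while (length(active) > 2) {
    m <- naive_genorm_m(mat[active, , drop = FALSE])
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[length(worst)]   # lexicographically later
    elim <- c(elim, worst)
    m_at_exit[worst] <- m[[worst]]
    active <- setdiff(active, worst)
  }
  pair <- sort(active)
  v <- naive_sd((-mat[pair[1], ]) - (-mat[pair[2], ]))
  m_at_exit[pair] <- v
  list(elimination = elim, final_pair = pair, m_at_exit = m_at_exit,
       pair_m = v)
}

naive_pairwise_variation <- function(mat, ranking) {
  lq <- t(sapply(rownames(mat), function(g) min(mat[g, ]) - mat[g, ]))
  rownames(lq) <- rownames(mat)
  k <- nrow(mat)
  v <- numeric(0)
  for (n in 2:(k - 1)) {
    nf_n <- apply(lq[ranking[1:n], , drop = FALSE], 2, mean)
    nf_n1 <- apply(lq[ranking[1:(n + 1)], , drop = FALSE], 2, mean)
    v[sprintf("V%d/%d", n, n + 1)] <- naive_sd(nf_n - nf_n1)
  }
  v
}

# NormFinder definitions, written out loop by loop
naive_normfinder <- function(mat, groups) {
  glab <- sort(unique(groups))
  stopifnot(length(glab) == 2)
  genes <- rownames(mat)
  k <- length(genes)
  G <- 2
  y <- t(sapply(genes, function(g) min(mat[g, ]) - mat[g, ]))
  rownames(y) <- genes

  ybar <- matrix(NA_real_, k, G, dimnames = list(genes, glab))
  sigma2 <- ybar
  n_g <- numeric(G)
  for (gi in 1:G) {
    cols <- which(groups == glab[gi])
    n <- length(cols); n_g[gi] <- n
    sub <- y[, cols, drop = FALSE]
    for (i in 1:k) ybar[i, gi] <- mean(sub[i, ])
    # two-way residuals within the group
    rmean <- sapply(1:k, function(i) mean(sub[i, ]))
    cmean <- sapply(1:n, function(j) mean(sub[, j]))
    tot <- mean(sub)
    s <- numeric(k)
    for (i in 1:k) {
      acc <- 0
      for (j in 1:n) acc <- acc + (sub[i, j] - rmean[i] - cmean[j] + tot)^2
      s[i] <- acc / (n - 1)
    }
    for (i in 1:k) {
      sigma2[i, gi] <- max(0, (s[i] - mean(s) / (k - 1)) * k / (k - 2))
    }
  }
  d <- matrix(NA_real_, k, G, dimnames = list(genes, glab))
  for (i in 1:k) for (gi in 1:G) {
    d[i, gi] <- ybar[i, gi] - mean(ybar[i, ]) - mean(ybar[, gi]) + mean(ybar)
  }
  var_d <- matrix(NA_real_, k, G, dimnames = list(genes, glab))
  for (gi in 1:G) {
    for (i in 1:k) {
      var_d[i, gi] <- sigma2[i, gi] / n_g[gi]
    }
  }
  gamma2 <- max(0, (sum(d^2) - sum(var_d)) / ((k - 1) * (G - 1)))
  rho <- numeric(k); names(rho) <- genes
  for (i in 1:k) {
    acc <- 0
    for (gi in 1:G) {
      if (gamma2 == 0) {
        # degenerate case: rank by the sampling SD of the group means
        acc <- acc + sqrt(sigma2[i, gi] / n_g[gi])
      } else {
        w <- gamma2 / (gamma2 + var_d[i, gi])
        acc <- acc + abs(d[i, gi] * w) + sqrt(var_d[i, gi] * w)
      }
    }
    rho[i] <- acc / G
  }
  list(rho = rho, d = d, sigma2 = sigma2, gamma2 = gamma2)
}

# --- fixture builders -------------------------------------------------

# collapsed two-group ct_table from a gene x sample matrix
matrix_ct_table <- function(mat, groups = NULL, template = "total") {
  samples <- colnames(mat)
  if (is.null(samples)) {
    samples <- paste0("s", seq_len(ncol(mat)))
    colnames(mat) <- samples
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  }
  if (is.null(groups)) {
    half <- ceiling(ncol(mat) / 2)
    groups <- rep(c("egg", "cortex"), c(half, ncol(mat) - half))
  }
  df <- expand.grid(gene = rownames(mat), sample = samples,
                    stringsAsFactors = FALSE)
  df$group <- groups[match(df$sample, samples)]
  df$template <- template
  df$replicate <- 1L
  df$ct <- mat[cbind(df$gene, df$sample)]
  ct_table(df)
}

# random Ct matrix with realistic structure (baselines 15-30, gene noise)
random_ct_matrix <- function(k, n, seed) {
  set.seed(seed)
  mu <- runif(k, 15, 30)
  sds <- runif(k, 0.1, 1.5)
  mat <- matrix(rnorm(k * n, mean = rep(mu, n), sd = rep(sds, n)), k, n)
  rownames(mat) <- paste0("g", seq_len(k))
  colnames(mat) <- paste0("s", seq_len(n))
  mat
}
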