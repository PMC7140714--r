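# Independent brute-force oracles used across the test files. These are
# deliberately naive (explicit loops, textbook formulas) and share no code
# with the package internals they check.

# Balanced 3-way ANOVA from explicit cell-mean sums of squares.
# y: response; A, B, C: factors. Returns F statistic and p per term.
oracle_anova3 <- function(y, A, B, C) {
  A <- factor(A); B <- factor(B); C <- factor(C)
  a <- nlevels(A); b <- nlevels(B); cc <- nlevels(C)
  n <- length(y) / (a * b * cc)  # balanced replicates per cell
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mC <- tapply(y, C, mean)
  mAB <- tapply(y, list(A, B), mean); mAC <- tapply(y, list(A, C), mean)
  mBC <- tapply(y, list(B, C), mean); mABC <- tapply(y, list(A, B, C), mean)

  ss <- list()
  ss$genotype  <- b * cc * n * sum((mA - gm)^2)
  ss$condition <- a * cc * n * sum((mB - gm)^2)
  ss$tissue    <- a * b * n * sum((mC - gm)^2)
  # interaction SS written out longhand
  sAB <- 0
  for (i in seq_len(a)) for (j in seq_len(b))
    sAB <- sAB + (mAB[i, j] - mA[i] - mB[j] + gm)^2
  ss$`genotype:condition` <- cc * n * sAB
  sAC <- 0
  for (i in seq_len(a)) for (k in seq_len(cc))
    sAC <- sAC + (mAC[i, k] - mA[i] - mC[k] + gm)^2
  ss$`genotype:tissue` <- b * n * sAC
  sBC <- 0
  for (j in seq_len(b)) for (k in seq_len(cc))
    sBC <- sBC + (mBC[j, k] - mB[j] - mC[k] + gm)^2
  ss$`condition:tissue` <- a * n * sBC
  sABC <- 0
  for (i in seq_len(a)) for (j in seq_len(b)) for (k in seq_len(cc))
    sABC <- sABC + (mABC[i, j, k] - mAB[i, j] - mAC[i, k] - mBC[j, k] +
                      mA[i] + mB[j] + mC[k] - gm)^2
  ss$`genotype:condition:tissue` <- n * sABC

  cell <- interaction(A, B, C)
  sse <- sum((y - ave(y, cell))^2)
  df <- c(a - 1, b - 1, cc - 1, (a - 1) * (b - 1), (a - 1) * (cc - 1),
          (b - 1) * (cc - 1), (a - 1) * (b - 1) * (cc - 1))
  names(df) <- names(ss)
  dfe <- length(y) - a * b * cc
  Fv <- mapply(function(s, d) (s / d) / (sse / dfe), unlist(ss), df)
  data.frame(term = names(ss), F = unname(Fv),
             p = unname(pf(Fv, df, dfe, lower.tail = FALSE)),
             stringsAsFactors = FALSE)
}

# Two-cell linear contrast under an independently fitted cell-means lm.
oracle_contrast <- function(y, cell, cell_hi, cell_lo) {
  fit <- lm(y ~ 0 + cell)
  cn <- paste0("cell", levels(cell))
  ct <- setNames(numeric(length(cn)), cn)
  ct[paste0("cell", cell_hi)] <- 1
  ct[paste0("cell", cell_lo)] <- -1
  est <- sum(ct * coef(fit))
  se <- sqrt(drop(t(ct) %*% vcov(fit) %*% ct))
  tt <- est / se
  list(estimate = est,
       p = 2 * pt(abs(tt), df.residual(fit), lower.tail = FALSE))
}

# Hypergeometric upper tail P(X >= k) by explicit binomial-coefficient sum.
oracle_hyper_tail <- function(k, N, m, n) {
  js <- k:min(n, m)
  if (k > min(n, m)) return(0)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# Conditioned degrees by an exhaustive double loop over the edge list.
oracle_conditioned_degrees <- function(edges, nodes, members) {
  deg_tot <- setNames(integer(length(nodes)), nodes)
  deg_set <- deg_tot
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    deg_tot[u] <- deg_tot[u] + 1L; deg_tot[v] <- deg_tot[v] + 1L
    if (v %in% members) deg_set[u] <- deg_set[u] + 1L
    if (u %in% members) deg_set[v] <- deg_set[v] + 1L
  }
  data.frame(node_id = nodes, degree_total = unname(deg_tot),
             degree_in_set = unname(deg_set), stringsAsFactors = FALSE)
}

# Venn regions by element-by-element membership scan.
oracle_partition_counts <- function(a, b, c = NULL) {
  if (is.null(c)) {
    u <- union(a, b)
    counts <- c(a_only = 0L, b_only = 0L, common = 0L)
    for (x in u) {
      ia <- x %in% a; ib <- x %in% b
      if (ia && ib) counts["common"] <- counts["common"] + 1L
      else if (ia) counts["a_only"] <- counts["a_only"] + 1L
      else counts["b_only"] <- counts["b_only"] + 1L
    }
    return(counts)
  }
  u <- union(union(a, b), c)
  counts <- c(a_only = 0L, b_only = 0L, c_only = 0L, ab = 0L, ac = 0L,
              bc = 0L, abc = 0L)
  for (x in u) {
    key <- paste0(ifelse(x %in% a, "a", ""), ifelse(x %in% b, "b", ""),
                  ifelse(x %in% c, "c", ""))
    slot <- switch(key, a = "a_only", b = "b_only", c = "c_only",
                   ab = "ab", ac = "ac", bc = "bc", abc = "abc")
    counts[slot] <- counts[slot] + 1L
  }
  counts
}

# small random ID sets for property-style tests
random_id_set <- function(n, pool = sprintf("id%03d", 1:60)) {
  sample(pool, n)
}
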