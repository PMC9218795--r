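# Independent oracle implementations used to check the package's
# computations. Each is written from the defining formula, not by calling
# the code path under test.

# Squared Pearson correlation from raw sums.
r2_brute <- function(x, y) {
  n <- length(x)
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num / den
}

# HWE exact p-value by direct log-choose enumeration of all heterozygote
# counts compatible with the allele counts.
hwe_brute <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n == 0 || rare == 0) return(1)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_het, hets)] * (1 + 1e-10)])
}

# Additive relationship by the recursive coefficient-of-kinship formula,
# memoised; independent of the tabular filling order.
a_recursive <- function(ped) {
  ids <- ped$animal
  sire <- setNames(ifelse(ped$sire %in% ids, ped$sire, NA), ids)
  dam <- setNames(ifelse(ped$dam %in% ids, ped$dam, NA), ids)
  memo <- new.env()
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    # order so that j is not an ancestor of i: use pedigree file order
    oi <- match(i, ids); oj <- match(j, ids)
    if (oi < oj) { tmp <- i; i <- j; j <- tmp }
    val <- if (i == j) {
      0.5 * (1 + kin(sire[[i]], dam[[i]]))
    } else {
      0.5 * (kin(sire[[i]], j) + kin(dam[[i]], j))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) for (b in a:n) {
    A[a, b] <- A[b, a] <- 2 * kin(ids[a], ids[b])
  }
  A
}

# Leftmost-maximal consecutive partition satisfying the all-pairs r2 >= t
# rule, by direct extent search with full double-loop pair checks.
blocks_exhaustive <- function(d, threshold) {
  m <- ncol(d)
  ok_run <- function(i, e) {
    for (a in i:(e - 1)) for (b in (a + 1):e) {
      if (cor(d[, a], d[, b])^2 < threshold) return(FALSE)
    }
    TRUE
  }
  blocks <- list(); singles <- integer(0)
  i <- 1L
  while (i <= m) {
    e <- i
    while (e + 1L <= m && ok_run(i, e + 1L)) e <- e + 1L
    if (e > i) blocks[[length(blocks) + 1L]] <- i:e else singles <- c(singles, i)
    i <- e + 1L
  }
  list(blocks = blocks, singles = singles)
}

# Naive double-loop VanRaden relationship matrix.
grm_naive <- function(mat, p = colMeans(mat) / 2) {
  n <- nrow(mat); m <- ncol(mat)
  div <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) s <- s + (mat[i, k] - 2 * p[k]) * (mat[j, k] - 2 * p[k])
    G[i, j] <- s / div
  }
  G
}

# Random small phased panel for property tests: polymorphic, non-duplicate
# columns, one chromosome.
random_panel <- function(n = 30, m = 8, seed = 1) {
  set.seed(seed)
  repeat {
    haps <- matrix(rbinom(2 * n * m, 1, runif(m, 0.15, 0.85)[rep(seq_len(m), each = 2 * n)]),
                   2 * n, m)
    # induce some local correlation so blocks can form
    if (m >= 2) for (j in 2:m) {
      copy <- rbinom(2 * n, 1, 0.6) == 1
      haps[copy, j] <- haps[copy, j - 1]
    }
    d <- haps[seq(1, 2 * n, 2), , drop = FALSE] +
      haps[seq(2, 2 * n, 2), , drop = FALSE]
    vars <- apply(d, 2, var)
    if (all(vars > 0) && !anyDuplicated(t(d))) break
  }
  map <- tibble::tibble(snp_id = sprintf("s%02d", 1:m), chrom = "chr1",
                        pos = seq_len(m) * 1000L, ref = "A", alt = "B",
                        pos_cm = seq_len(m) * 0.001)
  phased_genotypes(haps, sprintf("id%03d", 1:n), map)
}

# Corrected phenotypes joined with true breeding values for a sim dataset.
yc_with_tbv <- function(ds, fit) {
  yc <- corrected_phenotype(fit)
  yc$tbv <- ds$truth$true_breeding_values[yc$animal]
  yc
}
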