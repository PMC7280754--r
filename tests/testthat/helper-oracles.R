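# Independent brute-force oracles used to freeze expected values. These
# deliberately share no code with the package implementation: reverse
# complements are built from a lookup table, site scanning slides a window
# with substring comparison, and the hypergeometric CDF is an explicit
# factorial sum.

oracle_revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_patterns <- function(seed) {
  m8 <- oracle_revcomp(seed)
  a1 <- paste0(oracle_revcomp(substr(seed, 1, 6)), "A")
  c("8mer" = paste0(m8, "A"), "7mer-m8" = m8, "7mer-A1" = a1)
}

# all (overlapping) start positions of `pattern` in `utr` by direct
# substring comparison
oracle_positions <- function(pattern, utr) {
  w <- nchar(pattern)
  n <- nchar(utr)
  if (n < w) return(integer(0))
  starts <- seq_len(n - w + 1)
  starts[substring(utr, starts, starts + w - 1) == pattern]
}

# sliding-window scan of one UTR with the 8mer > 7mer-m8 > 7mer-A1
# precedence cascade applied by position arithmetic
oracle_scan_one <- function(seed, utr) {
  pats <- oracle_patterns(seed)
  kept <- data.frame(site_type = character(), utr_start = integer(),
                     utr_end = integer(), stringsAsFactors = FALSE)
  for (ty in c("8mer", "7mer-m8", "7mer-A1")) {
    starts <- oracle_positions(pats[[ty]], utr)
    ends <- starts + nchar(pats[[ty]]) - 1L
    keep <- rep(TRUE, length(starts))
    for (i in seq_along(starts))
      if (any(starts[i] <= kept$utr_end & ends[i] >= kept$utr_start))
        keep[i] <- FALSE
    if (any(keep))
      kept <- rbind(kept, data.frame(site_type = ty,
                                     utr_start = starts[keep],
                                     utr_end = ends[keep],
                                     stringsAsFactors = FALSE))
  }
  kept[order(kept$utr_start), , drop = FALSE]
}

# exact factorial-sum lower-tail CDF of the shared-target count:
# sum_{t=0}^{Nxy-1} C(Nx,t) C(N-Nx, Ny-t) / C(N, Ny)
oracle_overlap_cdf <- function(N, Nx, Ny, Nxy) {
  ch <- function(n, k) {
    if (k < 0 || k > n) return(0)
    factorial(n) / (factorial(k) * factorial(n - k))
  }
  if (Nxy == 0) return(0)
  total <- 0
  for (t in 0:(Nxy - 1))
    total <- total + ch(Nx, t) * ch(N - Nx, Ny - t)
  total / ch(N, Ny)
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all group splits
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(n, na)
  w <- apply(splits, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  center <- na * (n - na) / 2
  mean(abs(w - center) >= abs(obs - center))
}

# Jonckheere-Terpstra statistic by explicit pair counting
oracle_jt <- function(groups) {
  s <- 0
  for (i in seq_len(length(groups) - 1))
    for (j in (i + 1):length(groups))
      for (u in groups[[i]])
        for (v in groups[[j]])
          s <- s + (v > u) + 0.5 * (v == u)
  s
}

# hand log-rank over distinct event times: O/E/V accumulation
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (tj in sort(unique(time[event == 1]))) {
    at_risk <- time >= tj
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tj & event == 1)
    d1 <- sum(time == tj & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

random_rna_strings <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}
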