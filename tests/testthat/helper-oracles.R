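# Independent oracles used by the tests. Each reimplements the quantity it
# checks by a different route than the package (brute force, enumeration,
# term summation, Newton likelihood maximisation, matrix exponentials), so
# implementation and check never share code.

# average pairwise difference count, brute force over all chromosome pairs
# reconstructed from an unfolded spectrum (site i present on chromosomes
# 1..i; pairwise averages are invariant to the labelling)
oracle_pi_bruteforce <- function(sfs, n) {
  sites <- rep(seq_along(sfs), times = sfs)
  if (length(sites) == 0) return(0)
  geno <- vapply(sites, function(i) c(rep(1, i), rep(0, n - i)), numeric(n))
  tot <- 0
  np <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      tot <- tot + sum(geno[a, ] != geno[b, ])
      np <- np + 1
    }
  }
  tot / np
}

# Poisson upper tail P(X >= k) by direct summation of the upper-tail terms
# (term recurrence upward from x = k until negligible)
oracle_poisson_tail <- function(k, lambda) {
  if (k <= 0) return(1)
  term <- exp(k * log(lambda) - lambda - lgamma(k + 1))
  tot <- 0
  x <- k
  repeat {
    tot <- tot + term
    term <- term * lambda / (x + 1)
    x <- x + 1
    if (term < tot * 1e-18 + 1e-300) break
  }
  tot
}

# one-sided Fisher p by enumeration of all tables with the observed margins
oracle_fisher_enum <- function(a, b, c, d) {
  m1 <- a + b   # group-1 size
  cs <- a + c   # total successes
  n_tot <- a + b + c + d
  lo <- max(0, cs - (n_tot - m1))
  hi <- min(m1, cs)
  probs <- vapply(lo:hi, function(x) {
    choose(cs, x) * choose(n_tot - cs, m1 - x) / choose(n_tot, m1)
  }, numeric(1))
  sum(probs[(lo:hi) >= a])
}

# binomial GLM with fixed offset, maximised by Newton iterations on the
# log-likelihood with analytic gradient and Hessian
oracle_binom_newton <- function(X, succ, fail, offset = 0, maxit = 200) {
  beta <- rep(0, ncol(X))
  n <- succ + fail
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- plogis(eta)
    grad <- drop(crossprod(X, succ - n * mu))
    W <- n * mu * (1 - mu)
    H <- crossprod(X, W * X)
    delta <- solve(H, grad)
    beta <- beta + delta
    if (max(abs(delta)) < 1e-13) break
  }
  drop(beta)
}

# codon-column likelihood on a star tree by exhaustive enumeration over the
# 61 sense-codon root states, with transition matrices from Matrix::expm
# and the genetic code taken from Biostrings (independent of the package's
# internal tables)
oracle_codon_rate_matrix <- function(omega) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  aa <- code[sense]
  k <- length(sense)
  bases <- do.call(rbind, strsplit(sense, ""))
  Q <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sum(bases[i, ] != bases[j, ]) == 1) {
        r <- if (aa[i] == aa[j]) 1 else omega
        Q[i, j] <- Q[j, i] <- r
      }
    }
  }
  syn_flux <- sum(Q[outer(aa, aa, "==")]) / k
  Q <- Q / syn_flux
  diag(Q) <- -rowSums(Q)
  list(Q = Q, codons = sense)
}

oracle_star_likelihood <- function(tip_codons, branch_lengths, omega) {
  or <- oracle_codon_rate_matrix(omega)
  states <- match(tip_codons, or$codons)
  stopifnot(!anyNA(states))
  P <- lapply(branch_lengths, function(t) {
    as.matrix(Matrix::expm(or$Q * t))
  })
  lik <- 0
  for (root in seq_along(or$codons)) {
    term <- 1 / length(or$codons)
    for (tip in seq_along(states)) {
      term <- term * P[[tip]][root, states[tip]]
    }
    lik <- lik + term
  }
  log(lik)
}

# all-pairs minimum distance from 1-based point positions to 0-based
# half-open intervals: the number of bases strictly between the point and
# the interval (0 if inside or immediately adjacent)
oracle_point_region_distance <- function(chrom, pos, regions) {
  vapply(seq_along(pos), function(i) {
    r <- regions[regions$chrom == chrom[i], , drop = FALSE]
    if (nrow(r) == 0) return(NA_real_)
    d <- vapply(seq_len(nrow(r)), function(j) {
      if (pos[i] > r$start[j] && pos[i] <= r$end[j]) 0
      else if (pos[i] <= r$start[j]) r$start[j] - pos[i]
      else pos[i] - r$end[j] - 1
    }, numeric(1))
    min(d)
  }, numeric(1))
}

# a small star tree with equal branch lengths, dS-scaled
star_tree <- function(n_tips, total_ds = 12.2, labels = NULL) {
  if (is.null(labels)) labels <- c("human", sprintf("sp%02d", seq_len(n_tips - 1)))
  txt <- paste0("(", paste0(labels, ":1", collapse = ","), ");")
  scale_tree_ds(ape::read.tree(text = txt), total_ds)
}
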