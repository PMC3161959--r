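# Codon substitution model used by the conservation LRT.
#
# States are the 61 sense codons of the standard genetic code with uniform
# stationary frequencies. Instantaneous rates connect codons differing at a
# single nucleotide: synonymous exchanges at rate 1, nonsynonymous at rate
# omega; stop codons are disallowed. With uniform frequencies and unit
# synonymous exchangeabilities the synonymous flux per unit time is a
# constant independent of omega, so a single global normalisation puts
# branch lengths in synonymous-substitutions-per-site (dS) units: a tree
# whose branch lengths sum to ds_total has a tree-wide synonymous length of
# exactly ds_total for every omega.

codon_model_env <- new.env(parent = emptyenv())

standard_genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  # canonical ordering: base1 slowest, base3 fastest
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), times = 4), rep(b, times = 16))
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  setNames(aa, codons)
}

codon_model <- function() {
  if (!is.null(codon_model_env$model)) return(codon_model_env$model)
  code <- standard_genetic_code()
  sense <- names(code)[code != "*"]
  aa <- code[sense]
  k <- length(sense)  # 61
  bases <- do.call(rbind, strsplit(sense, ""))
  syn <- matrix(0, k, k)
  nonsyn <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sum(bases[i, ] != bases[j, ]) == 1L) {
        if (aa[i] == aa[j]) syn[i, j] <- syn[j, i] <- 1
        else nonsyn[i, j] <- nonsyn[j, i] <- 1
      }
    }
  }
  # synonymous flux per unit time before normalisation: sum_i pi_i sum_j syn_ij
  mu_s <- sum(syn) / k
  codon_model_env$model <- list(
    codons = sense, aa = aa, syn = syn, nonsyn = nonsyn, k = k,
    scale = 1 / mu_s
  )
  codon_model_env$model
}

codon_rate_matrix <- function(omega) {
  m <- codon_model()
  Q <- m$scale * (m$syn + omega * m$nonsyn)
  diag(Q) <- -rowSums(Q)
  Q
}

# Eigen-decomposition cache keyed by omega (Q is symmetric under uniform
# frequencies, so P(t) = V exp(D t) V').
codon_eigen <- function(omega) {
  key <- format(omega, digits = 17)
  hit <- codon_model_env$eigen_cache[[key]]
  if (!is.null(hit)) return(hit)
  E <- eigen(codon_rate_matrix(omega), symmetric = TRUE)
  if (is.null(codon_model_env$eigen_cache)) codon_model_env$eigen_cache <- list()
  if (length(codon_model_env$eigen_cache) > 400) codon_model_env$eigen_cache <- list()
  codon_model_env$eigen_cache[[key]] <- E
  E
}

codon_transition <- function(omega, t) {
  E <- codon_eigen(omega)
  P <- E$vectors %*% (exp(E$values * t) * t(E$vectors))
  P[P < 0] <- 0
  P
}

#' Encode codon strings as model states
#'
#' Maps codon triplets to indices among the 61 sense codons. Gaps (`"---"`,
#' `"-"`, `NA`, `""`) become `NA` (missing data); any other triplet that is
#' not an ACGT sense codon (ambiguity codes, stop codons) is also treated
#' as missing, and the number of such invalid codons is recorded in the
#' `"n_invalid"` attribute.
#'
#' @param x Character vector of codons (T/U accepted, case-insensitive).
#' @return Integer vector of states in `1..61` with `NA` for missing, with
#'   attribute `n_invalid`.
#' @export
encode_codons <- function(x) {
  m <- codon_model()
  x <- toupper(gsub("U", "T", toupper(as.character(x))))
  gap <- is.na(x) | x %in% c("---", "-", "", "...") | grepl("-", x, fixed = TRUE)
  st <- match(x, m$codons)
  n_invalid <- sum(is.na(st) & !gap)
  st[gap] <- NA_integer_
  attr(st, "n_invalid") <- n_invalid
  st
}

#' Scale a phylogeny to a fixed synonymous tree length
#'
#' Rescales all branch lengths proportionally so that they sum to
#' `ds_total` synonymous substitutions per site (default 12.2), the unit in
#' which the conservation LRT measures rates.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param ds_total Target tree-wide synonymous length.
#' @return The rescaled tree, with attribute `ds_total`.
#' @export
scale_tree_ds <- function(tree, ds_total = 12.2) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length), ds_total > 0)
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0")
  tot <- sum(tree$edge.length)
  if (tot <= 0) abort("tree has zero total length")
  tree$edge.length <- tree$edge.length * (ds_total / tot)
  attr(tree, "ds_total") <- ds_total
  tree
}

tree_ds_total <- function(tree) {
  attr(tree, "ds_total") %||% sum(tree$edge.length)
}

# Postorder pruning over all sites at once. `states` is an integer matrix
# (tips x sites) of codon states (NA = missing). Returns per-site
# log-likelihoods under uniform root frequencies.
codon_loglik_batch <- function(states, tree, omega) {
  k <- codon_model()$k
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  el <- tr$edge.length
  n_tip <- length(tr$tip.label)
  if (is.null(rownames(states))) {
    if (nrow(states) != n_tip) abort("states has no rownames and wrong row count")
    ord <- seq_len(n_tip)
  } else {
    ord <- match(tr$tip.label, rownames(states))
    if (anyNA(ord)) abort("states rownames must cover all tree tip labels")
  }
  S <- ncol(states)
  partial <- vector("list", max(edge))
  logscale <- vector("list", max(edge))
  tip_partial <- function(tip) {
    st <- states[ord[tip], ]
    M <- matrix(0, k, S)
    obs <- which(!is.na(st))
    M[cbind(st[obs], obs)] <- 1
    if (length(obs) < S) M[, setdiff(seq_len(S), obs)] <- 1
    M
  }
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]
    child <- edge[e, 2]
    P <- codon_transition(omega, el[e])
    if (child <= n_tip) {
      Lc <- P %*% tip_partial(child)
      sc <- rep(0, S)
    } else {
      Lc <- P %*% partial[[child]]
      sc <- logscale[[child]]
      partial[child] <- list(NULL)
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- Lc
      logscale[[parent]] <- sc
    } else {
      M <- partial[[parent]] * Lc
      s <- .colSums(M, k, S)
      s[s <= 0] <- 1
      partial[[parent]] <- M / rep(s, each = k)
      logscale[[parent]] <- logscale[[parent]] + sc + log(s)
    }
  }
  root <- edge[nrow(edge), 1]
  lik <- .colSums(partial[[root]], k, S) / k
  log(lik) + logscale[[root]]
}

#' Log-likelihood of one codon alignment column
#'
#' Computes the log-likelihood of a single codon column under the codon
#' substitution process on a fixed tree with nonsynonymous/synonymous rate
#' ratio `omega`, by pruning from the tips to the root. Gaps and invalid
#' codons are treated as missing data.
#'
#' @param column Named character vector of codons (names = tip labels), or
#'   an integer state vector from [encode_codons()] named by tip.
#' @param tree A tree scaled with [scale_tree_ds()] (branch lengths in dS
#'   units).
#' @param omega Nonsynonymous/synonymous rate ratio (`>= 0`).
#' @return The log-likelihood (a single number).
#' @export
site_likelihood <- function(column, tree, omega) {
  if (omega < 0) abort("omega must be >= 0")
  st <- if (is.character(column)) encode_codons(column) else as.integer(column)
  if ((attr(st, "n_invalid") %||% 0) > 0) {
    inform(sprintf("%d invalid codon(s) treated as missing data", attr(st, "n_invalid")))
  }
  if (sum(!is.na(st)) < 2) abort("column must have >= 2 non-gap codons")
  m <- matrix(st, ncol = 1, dimnames = list(names(column), NULL))
  codon_loglik_batch(m, tree, omega)
}

#' Simulate codon alignment columns on a tree
#'
#' Draws root codons uniformly from the 61 sense codons and evolves them
#' down the tree under the codon model, with a (possibly per-site) omega.
#'
#' @param tree A dS-scaled tree.
#' @param omega Scalar or per-site vector of rate ratios.
#' @param n_sites Number of columns to simulate (ignored when `omega` is a
#'   vector).
#' @param seed Optional RNG seed.
#' @return A character matrix (tips x sites) of codons, with the simulated
#'   `omega` vector as attribute `"omega"`.
#' @export
simulate_codon_columns <- function(tree, omega = 1, n_sites = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- codon_model()
  if (length(omega) == 1) omega <- rep(omega, n_sites)
  S <- length(omega)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]  # preorder
  el <- rev(tr$edge.length)
  n_tip <- length(tr$tip.label)
  root <- edge[1, 1]
  states <- matrix(NA_integer_, max(tr$edge), S)
  states[root, ] <- sample.int(m$k, S, replace = TRUE)
  groups <- split(seq_len(S), omega)
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]
    child <- edge[e, 2]
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      P <- codon_transition(omega[idx[1]], el[e])
      ps <- states[parent, idx]
      for (s in unique(ps)) {
        sel <- idx[ps == s]
        states[child, sel] <- sample.int(m$k, length(sel), replace = TRUE, prob = P[s, ])
      }
    }
  }
  out <- matrix(m$codons[states[seq_len(n_tip), , drop = FALSE]], n_tip, S)
  rownames(out) <- tr$tip.label
  attr(out, "omega") <- omega
  out
}
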