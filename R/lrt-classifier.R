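#' Per-codon conservation likelihood-ratio test
#'
#' Contrasts a neutral model in which the nonsynonymous rate equals the
#' synonymous rate (`omega = 1`) against a conserved model in which `omega`
#' is free, at a single codon alignment column on a fixed dS-scaled tree.
#' The statistic `2 (lnL_alt - lnL_null)` is referred to a chi-square with
#' one degree of freedom; a codon is flagged conserved when `p < p_cutoff`
#' (strict) and the estimated nonsynonymous rate is below the synonymous
#' rate (`omega_hat < 1`).
#'
#' @param column Named character vector of codons (names = tip labels).
#' @param tree A dS-scaled tree ([scale_tree_ds()]).
#' @param p_cutoff Significance cutoff for the conserved call (default
#'   0.001; ties at the cutoff are not conserved).
#' @param interval Search interval for `omega` (log-spaced bracketing).
#' @return A one-row tibble: `lnl_null`, `lnl_alt`, `omega_hat`, `dn_hat`
#'   (`omega_hat` times the synonymous tree length), `lrt_stat`, `p_value`,
#'   `conserved`.
#' @export
lrt_site <- function(column, tree, p_cutoff = 0.001, interval = c(1e-4, 10)) {
  st <- if (is.character(column)) encode_codons(column) else column
  names(st) <- names(column)
  if (sum(!is.na(st)) < 2) abort("column must have >= 2 non-gap codons")
  m <- matrix(st, ncol = 1, dimnames = list(names(st), NULL))
  f <- function(lw) codon_loglik_batch(m, tree, 10^lw)
  opt <- optimize(f, lower = log10(interval[1]), upper = log10(interval[2]),
                  maximum = TRUE, tol = 1e-4)
  lnl_null <- codon_loglik_batch(m, tree, 1)
  # the null is an interior point of the alternative space; never report a
  # worse alternative than the null itself (optimizer tolerance)
  lnl_alt <- max(opt$objective, lnl_null)
  omega_hat <- if (opt$objective >= lnl_null) 10^opt$maximum else 1
  lrt_result_row(lnl_null, lnl_alt, omega_hat, tree, p_cutoff)
}

lrt_result_row <- function(lnl_null, lnl_alt, omega_hat, tree, p_cutoff) {
  stat <- max(0, 2 * (lnl_alt - lnl_null))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  tibble(
    lnl_null = lnl_null, lnl_alt = lnl_alt, omega_hat = omega_hat,
    dn_hat = omega_hat * tree_ds_total(tree),
    lrt_stat = stat, p_value = p,
    conserved = (p < p_cutoff) & (omega_hat < 1)
  )
}

#' Conservation LRT over many codon columns
#'
#' Vectorised version of [lrt_site()]: shares transition-matrix
#' computations across sites by evaluating the likelihood of every column
#' on a dense log-spaced `omega` grid, then refining each site's maximum by
#' quadratic interpolation in `log10(omega)` around the best grid point.
#' With the default 121-point grid the refined log-likelihood is accurate
#' to well below 0.01, which is negligible against the chi-square cutoff;
#' `method = "optimize"` runs the slower per-site optimizer instead.
#'
#' @param states Integer state matrix (tips x sites) from
#'   [encode_codons()], rownames = tip labels; or a character codon matrix.
#' @param tree A dS-scaled tree.
#' @param p_cutoff Conserved-call cutoff (strict inequality).
#' @param method `"grid"` (default) or `"optimize"`.
#' @param grid Omega grid for `method = "grid"`.
#' @return A tibble with one row per column: `site`, `lnl_null`,
#'   `lnl_alt`, `omega_hat`, `dn_hat`, `lrt_stat`, `p_value`, `conserved`.
#' @export
lrt_sites <- function(states, tree, p_cutoff = 0.001,
                      method = c("grid", "optimize"),
                      grid = 10^seq(-4, 1, length.out = 121)) {
  method <- match.arg(method)
  if (is.character(states)) {
    rn <- rownames(states)
    states <- matrix(encode_codons(states), nrow(states), ncol(states))
    rownames(states) <- rn
  }
  S <- ncol(states)
  if (method == "optimize") {
    out <- map(seq_len(S), function(j) {
      col <- states[, j]
      names(col) <- rownames(states)
      lrt_site(col, tree, p_cutoff)
    }) %>% list_rbind()
    return(out %>% mutate(site = seq_len(S), .before = 1))
  }
  grid <- sort(unique(c(grid, 1)))
  lnl <- vapply(grid, function(w) codon_loglik_batch(states, tree, w),
                numeric(S))
  if (S == 1) lnl <- matrix(lnl, nrow = 1)
  lnl_null <- lnl[, which(grid == 1)]
  best <- max.col(lnl, ties.method = "first")
  lx <- log10(grid)
  lnl_alt <- numeric(S)
  omega_hat <- numeric(S)
  for (j in seq_len(S)) {
    b <- best[j]
    if (b == 1 || b == length(grid)) {
      lnl_alt[j] <- lnl[j, b]
      omega_hat[j] <- grid[b]
    } else {
      # quadratic through the three bracketing grid points, in log10(omega)
      x <- lx[(b - 1):(b + 1)]
      y <- lnl[j, (b - 1):(b + 1)]
      d1 <- (y[3] - y[1]) / (x[3] - x[1])
      d2 <- ((y[3] - y[2]) / (x[3] - x[2]) - (y[2] - y[1]) / (x[2] - x[1])) /
        ((x[3] - x[1]) / 2)
      if (d2 < 0) {
        xv <- x[2] - d1 / d2
        xv <- min(max(xv, x[1]), x[3])
        yv <- y[2] + d1 * (xv - x[2]) + 0.5 * d2 * (xv - x[2])^2
        lnl_alt[j] <- max(yv, y[2])
        omega_hat[j] <- 10^xv
      } else {
        lnl_alt[j] <- y[2]
        omega_hat[j] <- grid[b]
      }
    }
    if (lnl_alt[j] < lnl_null[j]) {
      lnl_alt[j] <- lnl_null[j]
      omega_hat[j] <- 1
    }
  }
  tibble(site = seq_len(S)) %>%
    bind_cols(
      map(seq_len(S), function(j) {
        lrt_result_row(lnl_null[j], lnl_alt[j], omega_hat[j], tree, p_cutoff)
      }) %>% list_rbind()
    )
}

translate_codon <- function(codon) {
  code <- standard_genetic_code()
  aa <- unname(code[toupper(gsub("U", "T", toupper(codon)))])
  aa[is.na(aa)] <- NA_character_
  aa
}

#' Classify one nonsynonymous SNP as deleterious, neutral, or untestable
#'
#' A nonsynonymous SNP is called deleterious when all three criteria hold:
#' (1) its codon is significantly conserved by the LRT (`p < 0.001`),
#' (2) the estimated nonsynonymous rate is below the synonymous rate
#' (`omega_hat < 1`), and (3) the derived amino acid is absent from the
#' orthologous position in all other (non-human) eutherian mammals. SNPs at
#' columns with fewer than 10 aligned eutherians are untestable.
#'
#' @param snp A list or one-row data frame with `ancestral_codon` and
#'   `derived_codon` (the human codon before/after the SNP).
#' @param site A one-row result from [lrt_site()]/[lrt_sites()] for the
#'   codon's column, or `NULL` when the column is absent (untestable).
#' @param column Named character vector of codons at the column (names =
#'   tip labels), used for criteria on eutherian residues.
#' @param eutherians Character vector of tip labels that are eutherian
#'   mammals.
#' @param human Tip label of the human row (excluded from criterion 3).
#' @return A one-row tibble: `call` in `deleterious`/`neutral`/
#'   `untestable`, plus logical reason flags `conserved_ok`, `omega_ok`,
#'   `residue_ok`, and `n_eutherians`.
#' @export
classify_snp <- function(snp, site, column, eutherians, human = "human") {
  anc <- translate_codon(snp$ancestral_codon)
  der <- translate_codon(snp$derived_codon)
  if (is.na(anc) || is.na(der)) abort("ancestral/derived codons must be sense codons")
  if (anc == der) abort("not a nonsynonymous SNP: ancestral and derived amino acids are identical")
  eut <- intersect(eutherians, names(column))
  st <- encode_codons(column[eut])
  n_eut <- sum(!is.na(st))
  if (is.null(site) || n_eut < 10) {
    return(tibble(call = "untestable", conserved_ok = NA, omega_ok = NA,
                  residue_ok = NA, n_eutherians = n_eut))
  }
  other <- setdiff(eut, human)
  other_aa <- translate_codon(column[other])
  conserved_ok <- isTRUE(site$p_value < 0.001)
  omega_ok <- isTRUE(site$omega_hat < 1)
  residue_ok <- !(der %in% other_aa[!is.na(other_aa)])
  call <- if (conserved_ok && omega_ok && residue_ok) "deleterious" else "neutral"
  tibble(call = call, conserved_ok = conserved_ok, omega_ok = omega_ok,
         residue_ok = residue_ok, n_eutherians = n_eut)
}

#' Classify a table of nonsynonymous SNPs against codon alignments
#'
#' Data-frame-first pipeline over [lrt_sites()] and [classify_snp()]: runs
#' the conservation LRT once per distinct codon column referenced by the
#' SNP table and joins the calls back on.
#'
#' @param snps Tibble with columns `snp_id`, `gene`, `codon_index`,
#'   `ancestral_codon`, `derived_codon`.
#' @param alignments Named list (by gene) of character codon matrices
#'   (tips x codon columns, rownames = tip labels).
#' @param tree A dS-scaled tree covering the alignment tips.
#' @param eutherians Character vector of eutherian tip labels.
#' @param human Human tip label.
#' @param method LRT method, see [lrt_sites()].
#' @return A tibble: `snp_id`, `call`, `p_value`, `omega_hat`,
#'   `n_eutherians` plus the criterion flags.
#' @export
classify_snps <- function(snps, alignments, tree, eutherians,
                          human = "human", method = "grid") {
  need <- snps %>% distinct(.data$gene, .data$codon_index)
  site_tbl <- need %>%
    group_by(.data$gene) %>%
    group_modify(function(d, key) {
      aln <- alignments[[key$gene]]
      present <- d$codon_index >= 1 & d$codon_index <= (if (is.null(aln)) 0 else ncol(aln))
      out <- tibble(codon_index = d$codon_index, p_value = NA_real_,
                    omega_hat = NA_real_, lrt_stat = NA_real_, absent = !present)
      if (any(present)) {
        res <- lrt_sites(aln[, d$codon_index[present], drop = FALSE], tree,
                         method = method)
        out$p_value[present] <- res$p_value
        out$omega_hat[present] <- res$omega_hat
        out$lrt_stat[present] <- res$lrt_stat
      }
      out
    }) %>%
    ungroup()
  joined <- snps %>% left_join(site_tbl, by = c("gene", "codon_index"))
  calls <- pmap(
    joined %>% select("gene", "codon_index", "ancestral_codon",
                      "derived_codon", "p_value", "omega_hat", "absent"),
    function(gene, codon_index, ancestral_codon, derived_codon,
             p_value, omega_hat, absent) {
      aln <- alignments[[gene]]
      col <- if (!absent) setNames(aln[, codon_index], rownames(aln)) else character(0)
      site <- if (!absent) tibble(p_value = p_value, omega_hat = omega_hat) else NULL
      classify_snp(list(ancestral_codon = ancestral_codon,
                        derived_codon = derived_codon),
                   site, col, eutherians, human)
    }
  ) %>% list_rbind()
  bind_cols(joined, calls) %>%
    select("snp_id", "gene", "codon_index", "call", "p_value", "omega_hat",
           "n_eutherians", "conserved_ok", "omega_ok", "residue_ok")
}
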