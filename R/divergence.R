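# Sequence and expression divergence between paralogs: Nei-Gojobori (1986)
# Ka/Ks with Jukes-Cantor correction, aligned protein identity, and
# 1 - Pearson expression divergence.

.pb_bases <- c("T", "C", "A", "G")
# standard genetic code, first codon position slowest, base order T C A G
.pb_code_str <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

pb_codon_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    codons <- character(64); k <- 0L
    for (b1 in .pb_bases) for (b2 in .pb_bases) for (b3 in .pb_bases) {
      k <- k + 1L; codons[k] <- paste0(b1, b2, b3)
    }
    aa <- strsplit(.pb_code_str, "")[[1L]]
    names(aa) <- codons
    # per-codon synonymous site counts (changes to stops count nonsynonymous)
    syn_sites <- numeric(64); names(syn_sites) <- codons
    for (cd in codons) {
      if (aa[[cd]] == "*") { syn_sites[[cd]] <- NA_real_; next }
      s <- 0
      nt <- strsplit(cd, "")[[1L]]
      for (pos in 1:3) for (alt in setdiff(.pb_bases, nt[pos])) {
        mut <- nt; mut[pos] <- alt
        mcd <- paste(mut, collapse = "")
        if (aa[[mcd]] != "*" && aa[[mcd]] == aa[[cd]]) s <- s + 1 / 3
      }
      syn_sites[[cd]] <- s
    }
    tab <<- list(codons = codons, aa = aa, syn_sites = syn_sites,
                 sense = codons[aa != "*"])
    tab
  }
})

#' Translate a codon to its amino acid (standard code)
#' @param codon 3-letter codon string(s), T/C/A/G alphabet.
#' @return single-letter amino acid(s); `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  pb_codon_table()$aa[toupper(codon)]
}

# All nine single-nucleotide mutants of each sense codon, classified as
# synonymous ("s"), nonsynonymous ("n") or stop-creating ("x"); used by the
# codon-pair simulator for O(1) mutation proposals.
pb_mut_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    ct <- pb_codon_table()
    tab <<- lapply(stats::setNames(ct$sense, ct$sense), function(cd) {
      nt <- strsplit(cd, "")[[1L]]
      new <- character(9L); type <- character(9L); k <- 0L
      for (pos in 1:3) for (alt in setdiff(.pb_bases, nt[pos])) {
        k <- k + 1L
        mut <- nt; mut[pos] <- alt
        mcd <- paste(mut, collapse = "")
        new[k] <- mcd
        type[k] <- if (ct$aa[[mcd]] == "*") "x"
                   else if (ct$aa[[mcd]] == ct$aa[[cd]]) "s" else "n"
      }
      list(new = new, type = type)
    })
    tab
  }
})

.pb_path_cache <- new.env(parent = emptyenv())

# Enumerate mutational pathways between two codons differing at >= 1 sites,
# averaging synonymous/nonsynonymous difference counts over all orderings of
# the changed positions with equal weights; pathways passing through a stop
# codon are discarded (if all are, all pathways are kept as a fallback).
codon_path_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- get0(key, .pb_path_cache)
  if (!is.null(hit)) return(hit)
  tab <- pb_codon_table()
  n1 <- strsplit(c1, "")[[1L]]; n2 <- strsplit(c2, "")[[1L]]
  diff_pos <- which(n1 != n2)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (nd == 1L) list(diff_pos) else
    lapply(asplit(perms(diff_pos), 1L), as.integer)
  acc <- list(); acc_any <- list()
  for (ord in paths) {
    cur <- n1; s <- 0; n <- 0; blocked <- FALSE
    for (pos in ord) {
      old <- paste(cur, collapse = "")
      cur[pos] <- n2[pos]
      new <- paste(cur, collapse = "")
      if (tab$aa[[new]] == "*" || tab$aa[[old]] == "*") blocked <- TRUE
      if (tab$aa[[new]] == tab$aa[[old]]) s <- s + 1 else n <- n + 1
    }
    acc_any[[length(acc_any) + 1L]] <- c(s, n)
    if (!blocked) acc[[length(acc) + 1L]] <- c(s, n)
  }
  use <- if (length(acc)) acc else acc_any
  m <- colMeans(do.call(rbind, use))
  out <- c(syn = m[[1L]], nonsyn = m[[2L]])
  assign(key, out, .pb_path_cache)
  out
}

# all permutations of a small vector (n <= 3 here)
perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Ka and Ks by the Nei-Gojobori (1986) pathway method
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence (averaged
#' over the pair) and synonymous/nonsynonymous differences per codon,
#' averaging with equal weights over all mutational pathways for codons
#' differing at 2-3 positions (pathways through stop codons discarded).
#' Proportions are corrected for multiple hits with Jukes-Cantor,
#' `d = -3/4 ln(1 - 4p/3)`; a proportion `p >= 3/4` leaves the estimate
#' undefined and flags saturation. A `ks > ks_saturation` estimate is also
#' flagged saturated (synonymous sites saturate long before nonsynonymous
#' ones).
#'
#' @param seq_a,seq_b aligned coding sequences (equal length, divisible by
#'   3, T/C/A/G/- alphabet; U is accepted and mapped to T). Codon columns
#'   containing a gap, an ambiguous base or a stop codon are dropped.
#' @param ks_saturation flag threshold on Ks, default 2.
#' @return a `divergence_estimate`: list with `ka`, `ks` (NA when
#'   undefined), `ka_ks`, `saturated`, `n_codons` (compared), `s_sites`,
#'   `n_sites`, `s_diffs`, `n_diffs`.
#' @export
ka_ks_ng86 <- function(seq_a, seq_b, ks_saturation = 2) {
  a <- toupper(gsub("U", "T", seq_a, ignore.case = TRUE))
  b <- toupper(gsub("U", "T", seq_b, ignore.case = TRUE))
  if (nchar(a) != nchar(b))
    pb_stop("alignment_error", "aligned sequences differ in length")
  if (nchar(a) %% 3L != 0L)
    pb_stop("alignment_error", "alignment length not divisible by 3")
  tab <- pb_codon_table()
  ca <- substring(a, seq(1L, nchar(a), 3L), seq(3L, nchar(a), 3L))
  cb <- substring(b, seq(1L, nchar(b), 3L), seq(3L, nchar(b), 3L))
  valid <- grepl("^[TCAG]{3}$", ca) & grepl("^[TCAG]{3}$", cb) &
    tab$aa[ca] != "*" & tab$aa[cb] != "*"
  valid[is.na(valid)] <- FALSE
  ca <- ca[valid]; cb <- cb[valid]
  if (!length(ca))
    pb_stop("alignment_error", "no comparable (ungapped, sense) codons in alignment")

  s_sites <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  n_sites <- 3 * length(ca) - s_sites
  sd_ <- 0; nd_ <- 0
  for (i in which(ca != cb)) {
    d <- codon_path_diffs(ca[[i]], cb[[i]])
    sd_ <- sd_ + d[["syn"]]; nd_ <- nd_ + d[["nonsyn"]]
  }
  ps <- sd_ / s_sites; pn <- nd_ / n_sites
  jc <- function(p) if (is.finite(p) && p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3)
                    else NA_real_
  ks <- jc(ps); ka <- jc(pn)
  saturated <- is.na(ks) || ks > ks_saturation
  structure(list(ka = ka, ks = ks,
                 ka_ks = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
                 saturated = saturated, n_codons = length(ca),
                 s_sites = s_sites, n_sites = n_sites,
                 s_diffs = sd_, n_diffs = nd_),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate> Ka = %.4f, Ks = %.4f over %d codons%s\n",
              x$ka, x$ks, x$n_codons, if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Aligned amino-acid identity
#'
#' Fraction of aligned columns carrying at least one residue in which both
#' sequences carry the same residue. Symmetric in argument order.
#'
#' @param seq_a,seq_b aligned amino-acid strings of equal length ('-' = gap).
#' @return identity fraction in \[0, 1\].
#' @export
protein_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(a) != length(b))
    pb_stop("alignment_error", "aligned sequences differ in length")
  occupied <- a != "-" | b != "-"
  if (!any(occupied)) pb_stop("alignment_error", "empty alignment")
  sum(a == b & a != "-" & occupied) / sum(occupied)
}

#' Expression divergence between two profiles
#'
#' Defined as 1 minus the Pearson correlation of the two expression profiles
#' over their shared finite conditions, so the value lies in \[0, 2\]
#' (0 = identical regulation, 2 = perfectly anti-correlated).
#'
#' @param profile_a,profile_b equal-length numeric condition vectors.
#' @return list with `value` (NA if undefined), `r`, `n` (conditions used)
#'   and `status` (`"ok"` or `"zero_variance"`).
#' @export
expression_divergence <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b))
    pb_stop("profile_error", "expression profiles differ in length")
  ok <- is.finite(profile_a) & is.finite(profile_b)
  a <- profile_a[ok]; b <- profile_b[ok]
  if (length(a) < 3L)
    pb_stop("profile_error", "fewer than 3 shared finite conditions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(value = NA_real_, r = NA_real_, n = length(a),
                status = "zero_variance"))
  r <- stats::cor(a, b)
  list(value = 1 - r, r = r, n = length(a), status = "ok")
}

#' Simulate an aligned codon pair with planted Ka and Ks
#'
#' Draws a random ancestor of sense codons and applies
#' `round(ks * S_sites)` synonymous and `round(ka * N_sites)` nonsynonymous
#' point substitutions (site counts taken on the ancestor), each at a
#' uniformly random position, in random order, split at random between the
#' two descendant copies. Repeated hits at a site arise naturally, so the
#' Jukes-Cantor correction in [ka_ks_ng86()] is exercised, not assumed.
#'
#' @param n_codons ancestor length in codons.
#' @param ks,ka planted substitutions per synonymous / nonsynonymous site.
#' @param seed optional integer seed.
#' @return list with `seq_a`, `seq_b` (aligned strings), `ks`, `ka`.
#' @export
simulate_codon_pair <- function(n_codons, ks, ka, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- pb_codon_table()
  anc <- sample(tab$sense, n_codons, replace = TRUE)
  s_sites <- sum(tab$syn_sites[anc]); n_sites <- 3 * n_codons - s_sites
  n_syn <- round(ks * s_sites); n_non <- round(ka * n_sites)
  mt <- pb_mut_table()
  seqs <- list(anc, anc)
  types <- sample(c(rep("s", n_syn), rep("n", n_non)))
  for (ty in types) {
    copy <- sample.int(2L, 1L)
    repeat {
      ci <- sample.int(n_codons, 1L)
      ent <- mt[[seqs[[copy]][[ci]]]]
      k <- sample.int(9L, 1L)
      if (ent$type[[k]] == ty) { seqs[[copy]][[ci]] <- ent$new[[k]]; break }
    }
  }
  list(seq_a = paste(seqs[[1L]], collapse = ""),
       seq_b = paste(seqs[[2L]], collapse = ""),
       ks = ks, ka = ka)
}
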