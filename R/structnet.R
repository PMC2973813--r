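# Structural and network properties of buffering pairs: secondary-structure
# transition vectors and their information discrepancy D; shared
# protein-interaction partners and protein-complex co-clustering.

.pb_ss_states <- c("H", "E", "C")
.pb_ss_pairs <- paste0(rep(.pb_ss_states, each = 3L), "->",
                       rep(.pb_ss_states, 3L))

#' Secondary-structure transition-probability vector
#'
#' Encodes a protein's secondary structure as the 9 first-order transition
#' probabilities among helices (H), strands (E) and coils (C):
#' `P(s -> t) = count(s followed by t) / count(s followed by anything)`.
#' Extended DSSP/PSIPRED codes are mapped (G, I -> H; B -> E;
#' T, S, '-', '.' -> C) with a message. Source states never visited yield
#' zero rows and are flagged.
#'
#' @param ss secondary-structure string.
#' @return an `ss_transition_vector`: list with `probs` (named 9-vector in
#'   H/E/C row order), `counts`, `unvisited` (source states with no
#'   outgoing transition).
#' @export
ss_transition_vector <- function(ss) {
  s <- strsplit(toupper(ss), "")[[1L]]
  mapped <- s
  mapped[s %in% c("G", "I")] <- "H"
  mapped[s == "B"] <- "E"
  mapped[s %in% c("T", "S", "-", ".")] <- "C"
  unknown <- !mapped %in% .pb_ss_states
  if (any(unknown)) {
    message(sprintf("ss_transition_vector: dropped %d character(s) outside H/E/C",
                    sum(unknown)))
    mapped <- mapped[!unknown]
  }
  if (length(mapped) < 2L)
    pb_stop("ss_input_error", "secondary-structure string shorter than 2 after mapping")
  from <- mapped[-length(mapped)]; to <- mapped[-1L]
  counts <- table(factor(from, .pb_ss_states), factor(to, .pb_ss_states))
  row_tot <- rowSums(counts)
  probs <- counts
  for (st in .pb_ss_states)
    probs[st, ] <- if (row_tot[[st]] > 0) counts[st, ] / row_tot[[st]] else 0
  v <- as.vector(t(probs)); names(v) <- .pb_ss_pairs
  cv <- as.vector(t(counts)); names(cv) <- .pb_ss_pairs
  structure(list(probs = v, counts = cv,
                 unvisited = .pb_ss_states[row_tot == 0]),
            class = "ss_transition_vector")
}

#' Information discrepancy D between two transition vectors
#'
#' Quantifies dissimilarity of two secondary structures as the
#' Jensen-Shannon divergence between their 9-entry transition vectors after
#' adding a small pseudocount (1e-6) and renormalizing each vector to a
#' probability distribution. D is symmetric, non-negative, bounded by ln 2,
#' and zero iff the vectors coincide; greater D means more dissimilar
#' structures.
#'
#' @param a,b `ss_transition_vector` objects (or bare 9-vectors).
#' @param pseudocount smoothing constant, default 1e-6.
#' @return D >= 0 (natural-log Jensen-Shannon divergence). The divergence
#'   formula used is recorded in the `"method"` attribute.
#' @export
structure_discrepancy <- function(a, b, pseudocount = 1e-6) {
  pa <- if (inherits(a, "ss_transition_vector")) a$probs else as.numeric(a)
  pb <- if (inherits(b, "ss_transition_vector")) b$probs else as.numeric(b)
  if (length(pa) != length(pb))
    pb_stop("input_error", "transition vectors differ in length")
  pa <- (pa + pseudocount) / sum(pa + pseudocount)
  pb <- (pb + pseudocount) / sum(pb + pseudocount)
  m <- (pa + pb) / 2
  kl <- function(p, q) sum(p * log(p / q))
  d <- kl(pa, m) / 2 + kl(pb, m) / 2
  structure(max(d, 0), method = "jensen_shannon_nat_log")
}

#' Build an undirected protein-protein interaction network
#'
#' @param edges data.frame (or 2-column matrix) of gene pairs, or a path to
#'   a 2-column TSV edge list (optional header `gene_a`, `gene_b`).
#' @return a `ppi_network`: list with `neighbors` (named list of neighbor
#'   sets; symmetric, self-loops dropped) and `n_edges`.
#' @export
ppi_network <- function(edges) {
  if (is.character(edges) && length(edges) == 1L && file.exists(edges)) {
    first <- readLines(edges, n = 1L)
    hdr <- grepl("gene", first, ignore.case = TRUE)
    edges <- utils::read.delim(edges, header = hdr, stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- pair_key(a, b)
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  nb <- lapply(split(c(b, a), c(a, b)), unique)
  structure(list(neighbors = nb, n_edges = length(a)), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d genes, %d edges\n",
              length(x$neighbors), x$n_edges))
  invisible(x)
}

pair_shares_partner <- function(net, gene_a, gene_b) {
  na <- net$neighbors[[gene_a]]; nb <- net$neighbors[[gene_b]]
  if (is.null(na) || is.null(nb)) return(NA)
  # the pair's own A-B edge is not a shared partner
  length(setdiff(intersect(na, nb), c(gene_a, gene_b))) > 0L
}

#' Compare shared-partner fractions of two pair groups
#'
#' For each group, computes the fraction of pairs whose two genes have at
#' least one common interaction partner (excluding the two genes
#' themselves, so a direct A-B edge does not count), then compares the two
#' fractions with a 2x2 chi-square test of independence (df = 1, no
#' continuity correction by default). Pairs with either gene absent from
#' the network are excluded and counted.
#'
#' @param group1,group2 data.frames with columns `gene_a`, `gene_b`.
#' @param net a `ppi_network`.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `frac1`, `frac2`, `n1`, `n2`, `shared1`, `shared2`,
#'   `chi2`, `p`, `excluded1`, `excluded2`.
#' @export
shared_partner_comparison <- function(group1, group2, net, correct = FALSE) {
  eval_group <- function(g) {
    sh <- mapply(pair_shares_partner, gene_a = g$gene_a, gene_b = g$gene_b,
                 MoreArgs = list(net = net))
    list(shared = sum(sh, na.rm = TRUE), n = sum(!is.na(sh)),
         excluded = sum(is.na(sh)))
  }
  g1 <- eval_group(group1); g2 <- eval_group(group2)
  if (g1$n == 0L || g2$n == 0L)
    pb_stop("empty_group_error", "a group has no pairs resolvable in the network")
  tab <- matrix(c(g1$shared, g1$n - g1$shared,
                  g2$shared, g2$n - g2$shared), 2L, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(frac1 = g1$shared / g1$n, frac2 = g2$shared / g2$n,
       n1 = g1$n, n2 = g2$n, shared1 = g1$shared, shared2 = g2$shared,
       chi2 = unname(ct$statistic), p = ct$p.value,
       excluded1 = g1$excluded, excluded2 = g2$excluded)
}

#' Read a protein-complex catalog
#'
#' @param x data.frame with columns `complex_id`, `gene`, or a path to such
#'   a TSV. Complexes with fewer than 2 members are dropped.
#' @return a `complex_catalog`: named list of gene sets.
#' @export
complex_catalog <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  sets <- lapply(split(as.character(x$gene), x$complex_id), unique)
  sets <- sets[vapply(sets, length, 1L) >= 2L]
  structure(sets, class = "complex_catalog")
}

#' Fraction of pairs co-clustered in a protein complex
#'
#' A pair co-clusters when both genes belong to at least one common
#' annotated complex.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param catalog a `complex_catalog`.
#' @return list with `fraction`, `n_cocluster`, `n_total`.
#' @export
complex_cocluster_fraction <- function(pairs, catalog) {
  if (!length(catalog)) pb_stop("empty_catalog_error", "complex catalog is empty")
  member <- new.env(parent = emptyenv())
  for (cx in names(catalog)) for (g in catalog[[cx]])
    assign(g, c(get0(g, member, ifnotfound = character()), cx), member)
  co <- mapply(function(a, b) {
    ca <- get0(a, member, ifnotfound = character())
    cb <- get0(b, member, ifnotfound = character())
    length(intersect(ca, cb)) > 0L
  }, pairs$gene_a, pairs$gene_b)
  list(fraction = mean(co), n_cocluster = sum(co), n_total = length(co))
}
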