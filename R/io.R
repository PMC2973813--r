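# Writers and readers for the plain-text formats the pipeline exchanges:
# OBO, GAF, TSV tables, FASTA, 2-line secondary structure.

#' Serialize an ontology DAG to OBO 1.2
#' @param dag an `ontology_dag`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    pars <- dag$parents[[t]]
    is_a <- if (length(pars)) pars[1L] else character()
    part_of <- if (length(pars) > 1L) pars[-1L] else character()
    out <- c(out, "[Term]",
             paste0("id: ", t),
             paste0("name: ", dag$name[[t]]),
             "namespace: biological_process",
             if (length(is_a)) paste0("is_a: ", is_a, " ! parent"),
             if (length(part_of)) paste0("relationship: part_of ", part_of, " ! parent"),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Serialize annotations to GAF 2.2
#' @param annotations data.frame with columns `gene`, `term`.
#' @param path output file.
#' @param evidence evidence code to stamp (default `"IDA"`; never `"IEA"`,
#'   which readers drop).
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, evidence = "IDA") {
  rows <- sprintf("SYN\t%s\t%s\t\t%s\tSYN:ref\t%s\t\tP\t\t\tgene\ttaxon:4932\t20090101\tSYN\t\t",
                  annotations$gene, annotations$gene, annotations$term, evidence)
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) pb_stop("fasta_format_error", "no FASTA headers found")
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  stats::setNames(unname(seqs), id)
}

#' Read a 2-line secondary-structure file (">gene" then the H/E/C string)
#' @param path input file.
#' @return named character vector of structure strings.
#' @export
read_ss_file <- function(path) read_fasta(path)

#' Write a synthetic fixture bundle to a directory
#'
#' Materializes the full output of [generate_pairs()] as the plain-text
#' files every reader in the package consumes — `ontology.obo`,
#' `annotations.gaf`, `pairs.tsv`, `interactions.tsv`, `cds.fasta`,
#' `expression.tsv`, `ss.txt`, `ppi.tsv`, `complexes.tsv` — plus
#' `manifest.json` recording the generating configuration and per-file MD5
#' checksums.
#'
#' @param dir output directory (created if needed).
#' @param config a [synth_config()].
#' @param bundle optional pre-generated [generate_pairs()] output (avoids
#'   regeneration).
#' @return the manifest list, invisibly.
#' @export
write_fixture_bundle <- function(dir, config, bundle = NULL) {
  if (is.null(bundle)) bundle <- generate_pairs(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_obo(bundle$dag, fp("ontology.obo"))
  write_gaf(bundle$annotations, fp("annotations.gaf"))
  wt <- function(df, f) utils::write.table(df, fp(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(bundle$pairs[, c("pair_id", "gene_a", "gene_b", "class",
                      "ks", "ka", "identity")], "pairs.tsv")
  wt(bundle$interactions, "interactions.tsv")
  write_fasta(bundle$cds, fp("cds.fasta"))
  expr <- data.frame(gene = rownames(bundle$expression),
                     bundle$expression, check.names = FALSE)
  wt(expr, "expression.tsv")
  write_fasta(bundle$ss, fp("ss.txt"))
  wt(bundle$ppi, "ppi.tsv")
  wt(bundle$complexes, "complexes.tsv")
  files <- c("ontology.obo", "annotations.gaf", "pairs.tsv",
             "interactions.tsv", "cds.fasta", "expression.tsv", "ss.txt",
             "ppi.tsv", "complexes.tsv")
  manifest <- list(
    config = unclass(bundle$config),
    checksums = as.list(tools::md5sum(vapply(files, fp, ""))),
    n_pairs = nrow(bundle$pairs)
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle directory back into memory
#' @param dir directory written by [write_fixture_bundle()].
#' @return list with `dag`, `corpus`, `pairs`, `interactions`,
#'   `expression`, `cds`, `ss`, `ppi`, `complexes`, `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  dag <- parse_obo(fp("ontology.obo"))
  corpus <- parse_gaf(fp("annotations.gaf"), dag)
  expr_df <- utils::read.delim(fp("expression.tsv"), check.names = FALSE)
  expr <- as.matrix(expr_df[, -1L])
  rownames(expr) <- expr_df$gene
  manifest <- if (file.exists(fp("manifest.json")))
    jsonlite::read_json(fp("manifest.json")) else NULL
  list(dag = dag, corpus = corpus,
       pairs = utils::read.delim(fp("pairs.tsv"), stringsAsFactors = FALSE),
       interactions = read_interaction_table(fp("interactions.tsv")),
       expression = expr,
       cds = read_fasta(fp("cds.fasta")),
       ss = read_ss_file(fp("ss.txt")),
       ppi = ppi_network(fp("ppi.tsv")),
       complexes = complex_catalog(fp("complexes.tsv")),
       manifest = manifest)
}
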