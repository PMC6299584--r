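# Germline V-gene repertoires, lineage assignment and mutation mapping.

#' Construct a germline V-gene record
#'
#' @param gene_name Gene name, e.g. `"1-84"`.
#' @param allele Allele designation, e.g. `"01"`.
#' @param v_region_sequence Amino-acid string of the V region.
#' @return Object of class `germline_gene`.
#' @export
germline_gene <- function(gene_name, allele, v_region_sequence) {
  .check_aa(v_region_sequence, sprintf("germline %s*%s", gene_name, allele))
  structure(list(gene_name = as.character(gene_name),
                 allele = as.character(allele),
                 v_region_sequence = v_region_sequence),
            class = "germline_gene")
}

#' @export
print.germline_gene <- function(x, ...) {
  cat(sprintf("Germline V gene %s*%s (%d aa)\n", x$gene_name, x$allele,
              nchar(x$v_region_sequence)))
  invisible(x)
}

germline_id <- function(g) paste0(g$gene_name, "*", g$allele)

#' Read a germline repertoire from FASTA
#'
#' Headers are expected in the form `gene*allele description`; a header with
#' no `*` is taken as a gene name with allele `"01"`.
#'
#' @param path FASTA file of amino-acid V-region sequences.
#' @return List of `germline_gene` objects.
#' @export
read_germline_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  lapply(seq_along(ss), function(i) {
    header <- names(ss)[i]
    idtok <- strsplit(header, "[ \t]")[[1]][1]
    parts <- strsplit(idtok, "*", fixed = TRUE)[[1]]
    germline_gene(parts[1], if (length(parts) > 1) parts[2] else "01",
                  as.character(ss[[i]]))
  })
}

#' Write a germline repertoire (or any named sequences) to FASTA
#'
#' @param x List of `germline_gene` objects, or a named character vector of
#'   sequences.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (length(x) && inherits(x[[1]], "germline_gene")) {
    seqs <- vapply(x, `[[`, character(1), "v_region_sequence")
    names(seqs) <- vapply(x, germline_id, character(1))
  } else {
    seqs <- unlist(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Assign a mature heavy chain to its germline V gene
#'
#' Every repertoire gene is globally aligned to the mature sequence and the
#' gene with the highest alignment score is returned. Score ties are broken
#' first in favour of genes named in `lineage_context` (genes already common
#' to sibling antibodies), then lexicographically by `gene*allele` name.
#'
#' @param mature_vh Amino-acid string of the mature VH domain.
#' @param repertoire List of `germline_gene` objects.
#' @param lineage_context Optional character vector of gene names favoured at
#'   score ties.
#' @param antibody_id Identifier carried into the result.
#' @return Object of class `lineage_assignment`: list with `antibody_id`,
#'   `best_gene`, `score`, `percent_identity`.
#' @export
assign_germline <- function(mature_vh, repertoire, lineage_context = NULL,
                            antibody_id = "query") {
  if (!length(repertoire)) stop("repertoire is empty", call. = FALSE)
  .check_aa(mature_vh, "mature_vh")
  alns <- lapply(repertoire, function(g) global_align(mature_vh, g$v_region_sequence))
  scores <- vapply(alns, `[[`, numeric(1), "score")
  ids <- vapply(repertoire, germline_id, character(1))
  in_ctx <- vapply(repertoire, function(g) g$gene_name %in% lineage_context,
                   logical(1))
  best <- max(scores)
  cand <- which(scores == best)
  if (length(cand) > 1L && any(in_ctx[cand]))
    cand <- cand[in_ctx[cand]]
  pick <- cand[order(ids[cand])][1L]
  out <- list(antibody_id = antibody_id,
              best_gene = repertoire[[pick]],
              score = scores[pick],
              percent_identity = percent_identity(alns[[pick]]))
  class(out) <- "lineage_assignment"
  out
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat(sprintf("%s -> %s (score %.1f, %.2f%% identity)\n", x$antibody_id,
              germline_id(x$best_gene), x$score, x$percent_identity))
  invisible(x)
}

#' Map somatic mutations between a germline and a mature chain
#'
#' Residues are compared at shared Kabat positions; one record is emitted per
#' position where the residues differ, labelled with the mature chain's CDR or
#' framework region. Terminal positions present in only one chain (germline V
#' regions end before CDR3/FW4 of the mature chain) are ignored.
#'
#' @param mature,germline `numbered_chain` objects of the same chain type.
#' @return data.frame with columns `kabat_position`, `germline_aa`,
#'   `mature_aa`, `region` (one row per substitution).
#' @export
map_mutations <- function(mature, germline) {
  stopifnot(inherits(mature, "numbered_chain"), inherits(germline, "numbered_chain"))
  if (mature$chain_type != germline$chain_type)
    stop("chain-type mismatch between mature and germline chains", call. = FALSE)
  m <- mature$residues
  g <- germline$residues
  shared <- intersect(m$label, g$label)
  mi <- match(shared, m$label)
  gi <- match(shared, g$label)
  diff <- which(m$aa[mi] != g$aa[gi])
  out <- data.frame(
    kabat_position = m$label[mi][diff],
    germline_aa = g$aa[gi][diff],
    mature_aa = m$aa[mi][diff],
    region = .cdr_label(mature, mi[diff]),
    stringsAsFactors = FALSE
  )
  out[order(.kabat_order_key(out$kabat_position)), , drop = FALSE]
}

#' Group antibodies by assigned germline V gene
#'
#' @param assignments List of `lineage_assignment` objects.
#' @return Named list mapping gene name to character vector of antibody ids,
#'   with attribute `singletons` flagging groups of size one (the lineage-level
#'   analyses drop antibodies that share no common germline origin).
#' @export
cluster_by_germline <- function(assignments) {
  if (!length(assignments)) return(structure(list(), singletons = character(0)))
  genes <- vapply(assignments, function(a) a$best_gene$gene_name, character(1))
  ids <- vapply(assignments, `[[`, character(1), "antibody_id")
  groups <- split(ids, genes)
  structure(groups, singletons = names(groups)[lengths(groups) == 1L])
}

#' Write a mutation table for several antibodies to CSV
#'
#' @param mutations Named list of data.frames from [map_mutations()].
#' @param path Output CSV.
#' @export
write_mutation_csv <- function(mutations, path) {
  rows <- lapply(names(mutations), function(ab) {
    df <- mutations[[ab]]
    if (!nrow(df)) return(NULL)
    cbind(antibody = ab, df)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(antibody = character(0), kabat_position = character(0),
                      germline_aa = character(0), mature_aa = character(0),
                      region = character(0))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
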