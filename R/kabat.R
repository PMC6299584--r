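# Kabat numbering by alignment to built-in variable-domain templates.
#
# CDR boundaries (Kabat): H1 31-35B, H2 50-65, H3 95-102,
#                         L1 24-34,  L2 50-56, L3 89-97.
# Insertion anchors: residues in excess of a region's canonical length are
# lettered at the region's anchor position (H: 35, 52, 82C, 100; L: 27, 95,
# 106); a shortfall drops canonical positions backwards from the anchor.

.kabat_pos <- function(number, insertion = "") {
  paste0(number, insertion)
}

.parse_kabat <- function(label) {
  num <- as.integer(sub("([0-9]+)[A-Z]?$", "\\1", label))
  ins <- sub("^[0-9]+", "", label)
  list(number = num, insertion = ins)
}

# ordering key: insertion absent < "A" < "B" < ...
.kabat_order_key <- function(labels) {
  p <- lapply(labels, .parse_kabat)
  num <- vapply(p, `[[`, integer(1), "number")
  ins <- vapply(p, `[[`, character(1), "insertion")
  num * 27 + ifelse(ins == "", 0L, match(ins, LETTERS))
}

# Region tables: canonical Kabat position labels per region, in order, plus
# the anchor label at which insertions are placed.
.kabat_regions <- function(chain_type) {
  lab <- function(from, to) as.character(from:to)
  if (chain_type == "H") {
    fw3 <- c(lab(66, 82), "82A", "82B", "82C", lab(83, 94))
    list(
      FW1  = list(pos = lab(1, 30),   anchor = "30"),
      CDR1 = list(pos = lab(31, 35),  anchor = "35"),
      FW2  = list(pos = lab(36, 49),  anchor = "49"),
      CDR2 = list(pos = lab(50, 65),  anchor = "52"),
      FW3  = list(pos = fw3,          anchor = "82C"),
      CDR3 = list(pos = lab(95, 102), anchor = "100"),
      FW4  = list(pos = lab(103, 113), anchor = "113")
    )
  } else {
    list(
      FW1  = list(pos = lab(1, 23),  anchor = "23"),
      CDR1 = list(pos = lab(24, 34), anchor = "27"),
      FW2  = list(pos = lab(35, 49), anchor = "49"),
      CDR2 = list(pos = lab(50, 56), anchor = "56"),
      FW3  = list(pos = lab(57, 88), anchor = "88"),
      CDR3 = list(pos = lab(89, 97), anchor = "95"),
      FW4  = list(pos = lab(98, 107), anchor = "106")
    )
  }
}

# Consensus-style template sequences (synthetic; one residue per canonical
# position, in region order).
.kabat_template_seq <- function(chain_type) {
  if (chain_type == "H") {
    c(FW1  = "EVQLQQSGAELVKPGASVKLSCKASGYTFT",
      CDR1 = "SYWMH",
      FW2  = "WVKQRPGQGLEWIG",
      CDR2 = "EINPSNGRTNYNEKFK",
      FW3  = "KATLTVDKSSSTAYMQLSSLTSEDSAVYYCAR",
      CDR3 = "EGYYGFDY",
      FW4  = "WGQGTTLTVSS")
  } else {
    c(FW1  = "DIVMTQSPSSLAVSAGEKVTMSC",
      CDR1 = "KSSQSLLNSRT",
      FW2  = "WYQQKPGQSPKLLIY",
      CDR2 = "WASTRES",
      FW3  = "GVPDRFTGSGSGTDFTLTISSVQAEDLAVYYC",
      CDR3 = "QQYYSYPLT",
      FW4  = "FGGGTKLEIK")
  }
}

#' Built-in Kabat reference template for a chain type
#'
#' @param chain_type `"H"` or `"L"`.
#' @return Amino-acid string of the template variable domain.
#' @export
kabat_template <- function(chain_type = c("H", "L")) {
  chain_type <- match.arg(chain_type)
  paste(.kabat_template_seq(chain_type), collapse = "")
}

# Assign Kabat labels to n residues of one region, deterministically.
.region_labels <- function(region, n) {
  pos <- region$pos
  m <- length(pos)
  a <- match(region$anchor, pos)
  if (n == m) return(pos)
  if (n > m) {
    anchor <- .parse_kabat(region$anchor)
    start_letter <- if (anchor$insertion == "") 0L else match(anchor$insertion, LETTERS)
    extra <- paste0(anchor$number, LETTERS[start_letter + seq_len(n - m)])
    return(c(pos[seq_len(a)], extra, if (a < m) pos[(a + 1L):m]))
  }
  # shortfall: drop d positions backwards starting at the anchor
  d <- m - n
  left <- pos[seq_len(a)]
  right <- if (a < m) pos[(a + 1L):m] else character(0)
  if (d > length(left))
    stop(sprintf("region too short to number (%d residues, canonical %d)", n, m),
         call. = FALSE)
  c(left[seq_len(a - d)], right)
}

#' Kabat-number an antibody variable-domain sequence
#'
#' The query is globally aligned to a built-in chain-type template; each query
#' residue inherits the region of its aligned template position (insertions
#' inherit the preceding region), then residues are renumbered within each
#' region by the canonical Kabat rule: positions beyond a region's canonical
#' length receive insertion letters at the region's anchor (e.g. 100A, 100B in
#' CDR-H3), shorter regions omit positions backwards from the anchor.
#'
#' @param sequence Amino-acid string of a single variable domain.
#' @param chain_type `"H"` (heavy) or `"L"` (light).
#' @param min_score Minimum alignment score to the template below which
#'   numbering fails.
#' @return An object of class `numbered_chain`: list with `chain_type`,
#'   `residues` (data.frame: `label`, `number`, `insertion`, `aa`, `region`)
#'   and `cdr_spans` (named list of `c(first_label, last_label)` per region).
#' @examples
#' nc <- kabat_number(kabat_template("H"), "H")
#' nc$cdr_spans$CDR2
#' @export
kabat_number <- function(sequence, chain_type = c("H", "L"), min_score = 50) {
  chain_type <- match.arg(chain_type)
  chars <- .check_aa(sequence, "sequence")
  template <- kabat_template(chain_type)
  aln <- global_align(sequence, template)
  if (aln$score < min_score)
    stop(sprintf(
      "numbering failure: alignment score %.1f to %s-chain template below %.1f",
      aln$score, chain_type, min_score), call. = FALSE)

  regions <- .kabat_regions(chain_type)
  # region label per template residue index
  tpl_region <- rep(names(regions), vapply(regions, function(r) length(r$pos),
                                           integer(1)))
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  ti <- 0L
  q_region <- character(0)
  for (k in seq_along(a)) {
    if (b[k] != "-") ti <- ti + 1L
    if (a[k] != "-") {
      reg <- if (ti == 0L) tpl_region[1L] else tpl_region[ti]
      q_region <- c(q_region, reg)
    }
  }
  stopifnot(length(q_region) == length(chars))
  # region membership must be contiguous in region order; enforce by taking
  # cumulative maximum over region rank (alignment can only move forward)
  rk <- cummax(match(q_region, names(regions)))
  q_region <- names(regions)[rk]

  labels <- character(length(chars))
  for (reg in names(regions)) {
    idx <- which(q_region == reg)
    if (!length(idx)) next
    labels[idx] <- .region_labels(regions[[reg]], length(idx))
  }
  p <- lapply(labels, .parse_kabat)
  residues <- data.frame(
    label = labels,
    number = vapply(p, `[[`, integer(1), "number"),
    insertion = vapply(p, `[[`, character(1), "insertion"),
    aa = chars,
    region = q_region,
    stringsAsFactors = FALSE
  )
  stopifnot(!is.unsorted(.kabat_order_key(residues$label), strictly = TRUE))
  spans <- lapply(split(residues$label, residues$region)[unique(residues$region)],
                  function(l) c(l[1], l[length(l)]))
  out <- list(chain_type = chain_type, residues = residues, cdr_spans = spans)
  class(out) <- "numbered_chain"
  out
}

#' @export
print.numbered_chain <- function(x, ...) {
  cat(sprintf("Kabat-numbered %s chain, %d residues\n",
              x$chain_type, nrow(x$residues)))
  for (reg in names(x$cdr_spans)) {
    idx <- x$residues$region == reg
    cat(sprintf("  %-4s %4s-%-4s %s\n", reg,
                x$cdr_spans[[reg]][1], x$cdr_spans[[reg]][2],
                paste(x$residues$aa[idx], collapse = "")))
  }
  invisible(x)
}

#' Sequence of a numbered chain
#' @param x A `numbered_chain`.
#' @return One-letter amino-acid string.
#' @export
chain_sequence <- function(x) {
  stopifnot(inherits(x, "numbered_chain"))
  paste(x$residues$aa, collapse = "")
}

# CDR region label ("H1".."L3" or "FW") for a chain's i-th residue
.cdr_label <- function(numbered, idx) {
  reg <- numbered$residues$region[idx]
  pre <- numbered$chain_type
  ifelse(grepl("^CDR", reg), paste0(pre, sub("CDR", "", reg)), "FW")
}
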