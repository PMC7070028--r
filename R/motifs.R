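# 3'UTR cis-element scanning: motif definitions, IUPAC matching, mutagenesis
# design and element-coverage summaries. Coordinates are 0-based, half-open.

IUPAC_RNA <- c(
  A = "A", C = "C", G = "G", U = "U",
  R = "AG", Y = "CU", S = "CG", W = "AU", K = "GU", M = "AC",
  B = "CGU", D = "AGU", H = "ACU", V = "ACG", N = "ACGU"
)

#' Define a 3'UTR sequence motif
#'
#' @param name Motif class label (e.g. `"DAZL"`, `"CPE"`, `"PAS"`). Several
#'   patterns may share a class name; class-level annotation pools them.
#' @param pattern IUPAC-degenerate string over the RNA alphabet
#'   (e.g. `"UUSUU"`, S = G or C).
#' @param source Free-text provenance tag for the consensus definition.
#' @return A one-row data frame (`name`, `pattern`, `source`).
#' @export
motif_def <- function(name, pattern, source = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  pattern <- toupper(gsub("T", "U", pattern, fixed = TRUE))
  if (!nzchar(pattern)) stop("motif pattern must be non-empty", call. = FALSE)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_RNA))
  if (length(bad) > 0) {
    stop(sprintf("motif '%s' contains non-IUPAC symbols: %s",
                 name, paste(bad, collapse = ", ")), call. = FALSE)
  }
  data.frame(name = name, pattern = pattern, source = source,
             stringsAsFactors = FALSE)
}

#' Default oocyte 3'UTR motif set
#'
#' The working consensus set: the DAZL binding element UU\[G/C\]UU (written
#' UUSUU), the cytoplasmic polyadenylation element (CPE, CPEB1 binding site)
#' in its two common forms, and the canonical/variant cleavage and
#' polyadenylation signals (PAS). Real scans should supply their own
#' config-driven set (see [read_motif_yaml()]); published consensus catalogues
#' (SELEX, crystal-structure, CLIP) differ in breadth.
#'
#' @return Data frame of motif definitions (`name`, `pattern`, `source`).
#' @export
default_motifs <- function() {
  rbind(
    motif_def("DAZL", "UUSUU",   "DAZL binding consensus, minimal form"),
    motif_def("CPE",  "UUUUAU",  "CPEB1 binding consensus"),
    motif_def("CPE",  "UUUUAAU", "CPEB1 binding consensus, extended"),
    motif_def("PAS",  "AAUAAA",  "canonical polyadenylation signal"),
    motif_def("PAS",  "AUUAAA",  "variant polyadenylation signal")
  )
}

#' Read a motif set from a YAML config
#'
#' Expects a top-level `motifs:` list of entries with `name`, `pattern` and
#' optional `source` fields.
#'
#' @param path Path to the YAML file.
#' @return Data frame of motif definitions.
#' @export
read_motif_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$motifs)) stop("YAML config has no 'motifs' entry", call. = FALSE)
  do.call(rbind, lapply(cfg$motifs, function(m) {
    motif_def(m$name, m$pattern, if (is.null(m$source)) "" else m$source)
  }))
}

# Validate an RNA sequence, converting DNA T to U (with a message). Errors
# name the first offending position.
normalize_rna <- function(seq, quiet = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("T", seq, fixed = TRUE)) {
    if (!quiet) message("DNA alphabet detected: converting T to U")
    seq <- gsub("T", "U", seq, fixed = TRUE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0) {
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  seq
}

iupac_to_regex <- function(pattern) {
  paste0(vapply(strsplit(pattern, "")[[1]], function(ch) {
    exp <- IUPAC_RNA[[ch]]
    if (nchar(exp) == 1L) exp else paste0("[", exp, "]")
  }, character(1)), collapse = "")
}

#' Scan an RNA sequence for motif matches
#'
#' Reports every window matching any pattern in the motif set, including
#' overlapping matches (no greedy masking): presence of at least one
#' consensus is the biologically relevant readout. Sense strand only.
#'
#' @param seq RNA string over A/C/G/U (DNA T is converted to U with a message).
#' @param motifs Motif definition data frame (default [default_motifs()]).
#' @param quiet Suppress the T-to-U conversion message.
#' @return Data frame of hits: `motif` (class name), `pattern`, `start`
#'   (0-based), `end` (exclusive), `matched` substring; sorted by
#'   (`start`, `motif`). Zero rows if nothing matches.
#' @export
scan_sequence <- function(seq, motifs = default_motifs(), quiet = FALSE) {
  seq <- normalize_rna(seq, quiet = quiet)
  hits <- lapply(seq_len(nrow(motifs)), function(i) {
    pat <- motifs$pattern[i]
    # lookahead regex so overlapping windows are all reported
    m <- gregexpr(paste0("(?=", iupac_to_regex(pat), ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    start0 <- as.integer(m) - 1L
    data.frame(motif = motifs$name[i], pattern = pat,
               start = start0, end = start0 + nchar(pat),
               matched = substring(seq, start0 + 1L, start0 + nchar(pat)),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(motif = character(0), pattern = character(0),
                       start = integer(0), end = integer(0),
                       matched = character(0), stringsAsFactors = FALSE)
  }
  hits[order(hits$start, hits$motif, hits$end), , drop = FALSE]
}

#' Annotate a single 3'UTR with element content
#'
#' Scans the sequence and summarises per-class hit counts, presence flags,
#' and for each DAZL/CPE hit the gap (nt) to the nearest downstream PAS
#' (start of the PAS minus end of the hit; `NA` when no PAS lies downstream).
#'
#' @param utr_id Identifier for the UTR.
#' @param seq RNA string.
#' @param motifs Motif definition data frame.
#' @return List with `hits` (the scan table plus `utr_id` and `dist_to_pas`)
#'   and `summary`, a one-row data frame with `utr_id`, `length`,
#'   `n_<class>` and `has_<class>` per motif class, plus `has_any_element`.
#' @export
annotate_utr <- function(utr_id, seq, motifs = default_motifs()) {
  seq <- normalize_rna(seq, quiet = TRUE)
  hits <- scan_sequence(seq, motifs, quiet = TRUE)
  classes <- unique(motifs$name)
  pas_starts <- hits$start[hits$motif == "PAS"]
  dist_to_pas <- rep(NA_real_, nrow(hits))
  if (length(pas_starts) > 0 && nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      if (hits$motif[i] == "PAS") next
      down <- pas_starts[pas_starts >= hits$end[i]]
      if (length(down) > 0) dist_to_pas[i] <- min(down) - hits$end[i]
    }
  }
  hits <- cbind(utr_id = rep(utr_id, nrow(hits)), hits,
                dist_to_pas = dist_to_pas, stringsAsFactors = FALSE)
  summary <- data.frame(utr_id = utr_id, length = nchar(seq),
                        stringsAsFactors = FALSE)
  for (cl in classes) {
    n <- sum(hits$motif == cl)
    summary[[paste0("n_", tolower(cl))]] <- n
    summary[[paste0("has_", tolower(cl))]] <- n > 0
  }
  summary$has_any_element <- nrow(hits) > 0
  list(hits = hits, summary = summary)
}

#' Annotate a set of 3'UTRs
#'
#' @param utrs Data frame with columns `utr_id` and `seq` (as returned by
#'   [generate_utr_set()] or [read_utr_fasta()]).
#' @param motifs Motif definition data frame.
#' @return List with `hits` (row-bound hit tables) and `summary` (one row
#'   per UTR).
#' @export
annotate_utrs <- function(utrs, motifs = default_motifs()) {
  ann <- lapply(seq_len(nrow(utrs)),
                function(i) annotate_utr(utrs$utr_id[i], utrs$seq[i], motifs))
  list(hits = do.call(rbind, lapply(ann, `[[`, "hits")),
       summary = do.call(rbind, lapply(ann, `[[`, "summary")))
}

#' Design an adenosine-replacement mutant for one motif hit
#'
#' Replaces nucleotides inside the hit window so the motif no longer matches,
#' leaving sequence length and all positions outside the window unchanged.
#' The default policy replaces every U in the window with A, the standard
#' way of destroying U-rich binding elements while minimally perturbing
#' composition. The mutant is re-scanned: if any hit of the same motif class
#' still overlaps the window, the policy is reported as insufficient.
#'
#' @param seq RNA string.
#' @param hit One-row data frame with `motif`, `start`, `end` (0-based,
#'   half-open), as produced by [scan_sequence()].
#' @param motifs Motif set used for the verification re-scan.
#' @param policy Function mapping the window string to a replacement of the
#'   same length; default U -> A.
#' @return The mutated RNA string.
#' @export
mutate_element <- function(seq, hit, motifs = default_motifs(),
                           policy = function(w) gsub("U", "A", w, fixed = TRUE)) {
  seq <- normalize_rna(seq, quiet = TRUE)
  start <- as.integer(hit$start[1]); end <- as.integer(hit$end[1])
  if (is.na(start) || is.na(end) || start < 0 || end > nchar(seq) || start >= end) {
    stop("hit window does not lie within the sequence", call. = FALSE)
  }
  window <- substring(seq, start + 1L, end)
  replacement <- policy(window)
  if (nchar(replacement) != nchar(window)) {
    stop("mutation policy changed the window length", call. = FALSE)
  }
  mutant <- paste0(substring(seq, 1L, start), replacement,
                   substring(seq, end + 1L, nchar(seq)))
  rescan <- scan_sequence(mutant, motifs, quiet = TRUE)
  same_class <- rescan[rescan$motif == hit$motif[1], , drop = FALSE]
  overlapping <- same_class$start < end & same_class$end > start
  if (any(overlapping)) {
    stop(sprintf("mutation policy insufficient: %s match still overlaps [%d, %d)",
                 hit$motif[1], start, end), call. = FALSE)
  }
  mutant
}

#' Element coverage over gene sets
#'
#' For each gene set and motif class, counts UTRs carrying at least one
#' element of that class. The question this answers: how many
#' translationally affected transcripts have no discernible binding element?
#'
#' @param annotations Annotation summary data frame ([annotate_utrs()]`$summary`).
#' @param gene_sets Named list of gene/UTR id vectors.
#' @return Data frame with one row per (set, class): `set`, `motif`,
#'   `n_with`, `n_without`, `n_no_utr` (ids missing from the annotations),
#'   `fraction` (of genes with a UTR that carry the element).
#' @export
element_coverage_summary <- function(annotations, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  classes <- sub("^has_", "", grep("^has_(?!any)", names(annotations),
                                   value = TRUE, perl = TRUE))
  out <- list()
  for (set_name in names(gene_sets)) {
    ids <- gene_sets[[set_name]]
    if (length(ids) == 0) {
      warning(sprintf("gene set '%s' is empty", set_name), call. = FALSE)
    }
    known <- ids[ids %in% annotations$utr_id]
    missing <- setdiff(ids, known)
    if (length(missing) > 0) {
      warning(sprintf("gene set '%s': %d ids have no UTR annotation",
                      set_name, length(missing)), call. = FALSE)
    }
    sub <- annotations[match(known, annotations$utr_id), , drop = FALSE]
    for (cl in classes) {
      n_with <- sum(sub[[paste0("has_", cl)]])
      out[[length(out) + 1L]] <- data.frame(
        set = set_name, motif = toupper(cl),
        n_with = n_with, n_without = length(known) - n_with,
        n_no_utr = length(missing),
        fraction = if (length(known) > 0) n_with / length(known) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write 3'UTR sequences as FASTA
#'
#' @param utrs Data frame with `utr_id`, `seq`, and optionally `desc`
#'   (carried into the FASTA description line).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  x <- Biostrings::RNAStringSet(utrs$seq)
  names(x) <- if (!is.null(utrs$desc)) {
    ifelse(nzchar(utrs$desc), paste(utrs$utr_id, utrs$desc), utrs$utr_id)
  } else utrs$utr_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read 3'UTR sequences from FASTA
#'
#' @param path FASTA file path (RNA or DNA alphabet; T is converted to U).
#' @return Data frame with `utr_id`, `seq`, `desc`.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  data.frame(utr_id = ids,
             seq = gsub("T", "U", toupper(as.character(x)), fixed = TRUE),
             desc = desc, stringsAsFactors = FALSE, row.names = NULL)
}
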