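# Synthetic 3'UTR generator with planted cis-elements and exact ground truth.
# Backgrounds are scrubbed of accidental motif matches so that scanning a
# generated set reproduces the planted element table exactly.

#' Specification for a synthetic 3'UTR set
#'
#' @param n_utrs Number of UTRs to generate.
#' @param length_range Length bounds in nt, `c(min, max)`.
#' @param gc_fraction Background GC content in \[0, 1\].
#' @param element_plan Named list, one entry per motif class to plant:
#'   `list(fraction = , copies = )`. `fraction` is the proportion of UTRs
#'   carrying the class; `copies` the number of non-overlapping elements per
#'   carrier. DAZL/CPE elements are placed upstream of the PAS when a PAS is
#'   planted (their biological position), the PAS near the 3' end.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return An object of class `utr_spec`.
#' @export
utr_spec <- function(n_utrs,
                     length_range = c(300L, 800L),
                     gc_fraction = 0.45,
                     element_plan = list(DAZL = list(fraction = 0.6, copies = 1),
                                         CPE  = list(fraction = 0.5, copies = 1),
                                         PAS  = list(fraction = 0.95, copies = 1)),
                     seed = 1L) {
  stopifnot(is.numeric(n_utrs), n_utrs >= 1,
            length(length_range) == 2L, all(length_range >= 1),
            length_range[1] <= length_range[2])
  stop_if_not_scalar_prob(gc_fraction, "gc_fraction")
  for (cl in names(element_plan)) {
    stop_if_not_scalar_prob(element_plan[[cl]]$fraction,
                            paste0("element_plan$", cl, "$fraction"))
    copies <- element_plan[[cl]]$copies
    stopifnot(is.numeric(copies), copies >= 1)
  }
  structure(list(n_utrs = as.integer(n_utrs),
                 length_range = as.integer(length_range),
                 gc_fraction = gc_fraction,
                 element_plan = element_plan,
                 seed = as.integer(seed)),
            class = "utr_spec")
}

random_background <- function(len, gc) {
  paste0(sample(c("A", "U", "G", "C"), len, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

# Remove all motif matches from a background sequence by resampling matched
# windows; bounded retries, then error naming the constraint.
scrub_background <- function(seq, motifs, gc, max_iter = 200L) {
  for (iter in seq_len(max_iter)) {
    hits <- scan_sequence(seq, motifs, quiet = TRUE)
    if (nrow(hits) == 0) return(seq)
    h <- hits[1, ]
    repl <- random_background(h$end - h$start, gc)
    seq <- paste0(substring(seq, 1L, h$start), repl,
                  substring(seq, h$end + 1L, nchar(seq)))
  }
  stop("rejection sampling failed: could not produce a motif-free background",
       call. = FALSE)
}

# One concrete instance of a degenerate IUPAC pattern, sampled uniformly.
realize_pattern <- function(pattern) {
  paste0(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- strsplit(IUPAC_RNA[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Generate a synthetic 3'UTR set with planted elements
#'
#' Backgrounds are i.i.d. nucleotides at the requested GC content, scrubbed of
#' accidental matches to every class in the motif set; planted elements are
#' concrete realisations of the class consensus spliced in at recorded
#' positions. Each UTR is verified by re-scanning: the generated hit table
#' must equal the planted one exactly (bounded retries otherwise), so the
#' truth table is self-consistent by construction and "element-free" UTRs are
#' genuinely element-free.
#'
#' @param spec A [utr_spec()].
#' @param motifs Motif set defining the classes (default [default_motifs()]).
#' @param carriers Optional named list (class -> logical vector of length
#'   `n_utrs`) overriding the random carrier draw, e.g. to tie element
#'   presence to gene classes planted elsewhere.
#' @param max_tries Retries per UTR before giving up.
#' @return List with `utrs` (data frame `utr_id`, `seq`, `desc`) and `truth`:
#'   `$elements` (utr_id, motif, start, end, instance) and `$carriers`
#'   (utr_id, length, plus `carries_<class>` flags).
#' @export
generate_utr_set <- function(spec, motifs = default_motifs(), carriers = NULL,
                             max_tries = 50L) {
  stopifnot(inherits(spec, "utr_spec"))
  plan <- spec$element_plan
  max_pat <- max(nchar(motifs$pattern))
  if (max_pat > spec$length_range[1]) {
    stop(sprintf("motif length %d exceeds minimum UTR length %d",
                 max_pat, spec$length_range[1]), call. = FALSE)
  }
  with_seed(spec$seed, {
    ids <- sprintf("utr%04d", seq_len(spec$n_utrs))
    carry <- lapply(names(plan), function(cl) {
      if (!is.null(carriers[[cl]])) {
        stopifnot(length(carriers[[cl]]) == spec$n_utrs)
        as.logical(carriers[[cl]])
      } else {
        stats::runif(spec$n_utrs) < plan[[cl]]$fraction
      }
    })
    names(carry) <- names(plan)

    seqs <- character(spec$n_utrs)
    elem_rows <- list()
    lens <- integer(spec$n_utrs)
    for (i in seq_len(spec$n_utrs)) {
      len <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
      lens[i] <- len
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        bg <- scrub_background(random_background(len, spec$gc_fraction),
                               motifs, spec$gc_fraction)
        planted <- plant_elements(bg, plan, carry, i, motifs)
        if (is.null(planted)) next
        rescan <- scan_sequence(planted$seq, motifs, quiet = TRUE)
        want <- planted$elements[order(planted$elements$start,
                                       planted$elements$motif), , drop = FALSE]
        if (nrow(rescan) == nrow(want) &&
            all(rescan$motif == want$motif) &&
            all(rescan$start == want$start) &&
            all(rescan$end == want$end)) {
          seqs[i] <- planted$seq
          if (nrow(want) > 0) {
            want$utr_id <- ids[i]
            elem_rows[[length(elem_rows) + 1L]] <- want
          }
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("could not plant elements cleanly in UTR %d after %d tries",
                     i, max_tries), call. = FALSE)
      }
    }

    elements <- if (length(elem_rows) > 0) {
      e <- do.call(rbind, elem_rows)
      e[, c("utr_id", "motif", "start", "end", "instance")]
    } else {
      data.frame(utr_id = character(0), motif = character(0),
                 start = integer(0), end = integer(0),
                 instance = character(0), stringsAsFactors = FALSE)
    }
    carriers_df <- data.frame(utr_id = ids, length = lens,
                              stringsAsFactors = FALSE)
    desc <- rep("", spec$n_utrs)
    for (cl in names(carry)) {
      carriers_df[[paste0("carries_", tolower(cl))]] <- carry[[cl]]
      desc <- paste0(desc, tolower(cl), "=", as.integer(carry[[cl]]), ";")
    }
    list(utrs = data.frame(utr_id = ids, seq = seqs, desc = desc,
                           stringsAsFactors = FALSE),
         truth = list(elements = elements, carriers = carriers_df))
  })
}

# Place planted element instances into a scrubbed background; NULL when a
# non-overlapping placement could not be found (caller retries).
plant_elements <- function(bg, plan, carry, i, motifs) {
  len <- nchar(bg)
  occupied <- matrix(numeric(0), ncol = 2)
  rows <- list()
  seq_out <- bg
  pas_start <- NA_integer_

  place_one <- function(lo, hi, w) {
    # candidate starts (0-based) leaving a 1-nt buffer around occupied windows
    cand <- seq.int(lo, hi)
    if (nrow(occupied) > 0) {
      bad <- rep(FALSE, length(cand))
      for (k in seq_len(nrow(occupied))) {
        bad <- bad | (cand < occupied[k, 2] + 1 & cand + w > occupied[k, 1] - 1)
      }
      cand <- cand[!bad]
    }
    if (length(cand) == 0) return(NA_integer_)
    if (length(cand) == 1) cand else sample(cand, 1L)
  }

  classes <- names(plan)
  # PAS first so upstream placement of regulatory elements is well-defined
  classes <- c(intersect("PAS", classes), setdiff(classes, "PAS"))
  for (cl in classes) {
    if (!carry[[cl]][i]) next
    pats <- motifs$pattern[motifs$name == cl]
    for (copy in seq_len(plan[[cl]]$copies)) {
      inst <- realize_pattern(sample(pats, 1L))
      w <- nchar(inst)
      if (cl == "PAS") {
        lo <- max(0L, len - w - 40L); hi <- len - w - 15L
        if (hi < lo) hi <- len - w
      } else if (!is.na(pas_start)) {
        lo <- 0L; hi <- pas_start - w - 2L
      } else {
        lo <- 0L; hi <- len - w
      }
      if (hi < lo) return(NULL)
      s <- place_one(lo, hi, w)
      if (is.na(s)) return(NULL)
      if (cl == "PAS" && is.na(pas_start)) pas_start <- s
      occupied <- rbind(occupied, c(s, s + w))
      seq_out <- paste0(substring(seq_out, 1L, s), inst,
                        substring(seq_out, s + w + 1L, len))
      rows[[length(rows) + 1L]] <- data.frame(
        motif = cl, start = s, end = s + w, instance = inst,
        stringsAsFactors = FALSE)
    }
  }
  elements <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(motif = character(0), start = integer(0), end = integer(0),
               instance = character(0), stringsAsFactors = FALSE)
  list(seq = seq_out, elements = elements)
}
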