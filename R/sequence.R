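# Annotation of bulged G4-forming sequences and expected unfolding step sizes
# per folding topology. Sequences are written the way the study's sequence
# table prints them: whitespace separates the four G-tract groups, e.g.
# "TTGTGGT GGGT GGGT GGGT". Every guanine inside a group is a tetrad-core
# guanine (three per tract, 12 in total for three-tetrad designs); non-G
# bases between the guanines of one tract form the bulge.

#' Parse a tract-grouped G4-forming sequence
#'
#' @param name Sequence name (e.g. `"TB-1"`).
#' @param sequence 5'->3' DNA string over ACGT, with whitespace delimiting the
#'   four G-tract groups. Each group must contain exactly three guanines.
#' @return Object of class `g4_sequence` with fields `name`, `sequence` (the
#'   concatenated, ungrouped string), `tract_guanines` (1-based positions of
#'   the 12 tetrad-core guanines), `bulge_position` (index 1-8 of the guanine
#'   pair gap holding the bulge, or `NA` if none) and `bulge_length` (nt).
#' @examples
#' tb1 <- parse_tract_sequence("TB-1", "TTGTGGT GGGT GGGT GGGT")
#' tb1$tract_guanines
#' expected_step_nt(tb1, "full")
#' @export
parse_tract_sequence <- function(name, sequence) {
  seq_up <- toupper(sequence)
  if (grepl("[^ACGT[:space:]]", seq_up)) {
    stop("sequence contains non-ACGT characters: ", name)
  }
  groups <- strsplit(trimws(seq_up), "[[:space:]]+")[[1]]
  if (length(groups) != 4) {
    stop("expected four whitespace-delimited G-tract groups, got ",
         length(groups), " for ", name)
  }
  concat <- paste(groups, collapse = "")
  offsets <- c(0, cumsum(nchar(groups)))[1:4]

  core <- integer(0)
  bulge_position <- NA_integer_
  bulge_length <- 0L
  for (i in seq_along(groups)) {
    g_local <- which(strsplit(groups[i], "")[[1]] == "G")
    if (length(g_local) != 3) {
      stop("tract group ", i, " of ", name, " has ", length(g_local),
           " guanines; expected 3")
    }
    core <- c(core, offsets[i] + g_local)
    # gaps between consecutive core guanines within this tract are bulges
    for (j in 1:2) {
      gap <- g_local[j + 1] - g_local[j] - 1L
      if (gap > 0) {
        if (!is.na(bulge_position)) {
          stop("more than one bulge found in ", name)
        }
        bulge_position <- 2L * (i - 1L) + j
        bulge_length <- gap
      }
    }
  }
  stopifnot(all(diff(core) > 0),
            all(substring(concat, core, core) == "G"))
  structure(
    list(name = name, sequence = concat, tract_guanines = core,
         bulge_position = bulge_position, bulge_length = bulge_length),
    class = "g4_sequence"
  )
}

#' Expected unfolding step size in nucleotides
#'
#' Number of nucleotides released when a given folding topology of the
#' sequence unfolds, counted as the inclusive span between the outermost
#' *structured* tetrad-core guanines (loops and internal bulges are inside
#' the span; dangling tails are not):
#' * `"full"` - fully-folded G4, all 12 core guanines structured;
#' * `"gvbq_5p"` - guanine-vacancy intermediate with the 5'-terminal core
#'   guanine flipped out;
#' * `"gvbq_3p"` - the 3'-terminal core guanine flipped out.
#'
#' @param annotation A `g4_sequence` from [parse_tract_sequence()].
#' @param topology One of `"full"`, `"gvbq_5p"`, `"gvbq_3p"`.
#' @return Integer nucleotide count.
#' @export
expected_step_nt <- function(annotation,
                             topology = c("full", "gvbq_5p", "gvbq_3p")) {
  stopifnot(inherits(annotation, "g4_sequence"))
  topology <- match.arg(topology)
  pos <- annotation$tract_guanines
  if (length(pos) < 2) stop("need at least two core guanines")
  n <- length(pos)
  span <- switch(topology,
    full    = pos[n] - pos[1] + 1L,
    gvbq_5p = pos[n] - pos[2] + 1L,
    gvbq_3p = pos[n - 1] - pos[1] + 1L
  )
  as.integer(span)
}

#' Packaged bulged-G4 sequence set
#'
#' Reads the packaged table of 27 bulged G4-forming sequences (T30695 and its
#' single- and multi-nucleotide bulge variants) and parses each entry.
#'
#' @param path Path to a two-column TSV (`name`, `sequence` with
#'   space-delimited tract groups). Defaults to the packaged file.
#' @return Named list of `g4_sequence` objects.
#' @export
load_g4_sequences <- function(path = system.file("extdata",
                                                 "g4_bulge_sequences.tsv",
                                                 package = "g4tweezers")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sequence") %in% names(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    parse_tract_sequence(tab$name[i], tab$sequence[i])
  })
  names(out) <- tab$name
  out
}
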