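#' Build a strand set
#'
#' A strand set is a tibble with one row per oligonucleotide: a unique `name`,
#' a `sequence` written 5'->3' over the DNA alphabet `{A, C, G, T}`, and a
#' `role`, either `"beacon"` (the hairpin molecular beacon carrying the
#' fluorophore/quencher pair) or `"input"` (a trigger strand whose presence
#' encodes a logic 1). A complete set contains exactly one beacon; subsets
#' built for individual input combinations keep the beacon and drop absent
#' inputs.
#'
#' @param name Character vector of unique strand identifiers.
#' @param sequence Character vector of DNA sequences, 5'->3', uppercase ACGT.
#' @param role Character vector, each `"beacon"` or `"input"`.
#' @param require_beacon Require exactly one beacon row (default `TRUE`).
#' @return A tibble of class `strand_set` with columns `name`, `sequence`,
#'   `role`.
#' @examples
#' strand_set(
#'   name = c("MB", "IN 1"),
#'   sequence = c("GCAGTCAAACATACCTCAAATCCAGACTGC", "TGGAGGTATGTTTGAC"),
#'   role = c("beacon", "input")
#' )
#' @export
strand_set <- function(name, sequence, role, require_beacon = TRUE) {
  out <- tibble::tibble(
    name = as.character(name),
    sequence = toupper(as.character(sequence)),
    role = as.character(role)
  )
  class(out) <- c("strand_set", class(out))
  validate_strand_set(out, require_beacon = require_beacon)
  out
}

#' Coerce a data frame to a strand set
#'
#' @param x A data frame with columns `name`, `sequence`, `role`.
#' @inheritParams strand_set
#' @return A `strand_set` tibble.
#' @export
as_strand_set <- function(x, require_beacon = TRUE) {
  stopifnot(all(c("name", "sequence", "role") %in% names(x)))
  strand_set(x$name, x$sequence, x$role, require_beacon = require_beacon)
}

validate_strand_set <- function(x, require_beacon = TRUE) {
  if (nrow(x) == 0) {
    return(invisible(x))
  }
  check_dna(x$sequence)
  if (anyDuplicated(x$name)) {
    stop("strand names must be unique within a strand set", call. = FALSE)
  }
  if (!all(x$role %in% c("beacon", "input"))) {
    stop("strand role must be 'beacon' or 'input'", call. = FALSE)
  }
  n_beacon <- sum(x$role == "beacon")
  if (require_beacon && n_beacon != 1L) {
    stop("a strand set must contain exactly one beacon strand", call. = FALSE)
  }
  if (!require_beacon && n_beacon > 1L) {
    stop("a strand set may contain at most one beacon strand", call. = FALSE)
  }
  invisible(x)
}

check_dna <- function(sequence) {
  if (any(is.na(sequence)) || any(nchar(sequence) == 0)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad)) {
    stop(
      "invalid alphabet: sequences must contain only A, C, G, T (got ",
      paste(unique(unlist(strsplit(gsub("[ACGT]", "", sequence[bad]), ""))),
        collapse = ", "
      ), ")",
      call. = FALSE
    )
  }
  invisible(sequence)
}

beacon_name <- function(strands) {
  strands$name[strands$role == "beacon"][1]
}

#' Subset a strand set to the strands present in one input combination
#'
#' @param strands A `strand_set`.
#' @param present Character vector of input strand names that are present.
#'   The beacon is always kept.
#' @return A `strand_set` tibble.
#' @export
subset_strands <- function(strands, present) {
  missing <- setdiff(present, strands$name)
  if (length(missing) > 0) {
    stop(
      "strand(s) not in set: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- strands$role == "beacon" | strands$name %in% present
  out <- strands[keep, , drop = FALSE]
  class(out) <- c("strand_set", setdiff(class(out), "strand_set"))
  out
}

#' Reverse complement of DNA sequences
#'
#' @param sequence Character vector of DNA sequences (uppercase ACGT).
#' @return Character vector of Watson-Crick reverse complements, 5'->3'.
#' @examples
#' reverse_complement("GGGT") # "ACCC"
#' @export
reverse_complement <- function(sequence) {
  check_dna(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

complement_base <- function(base) {
  c(A = "T", C = "G", G = "C", T = "A")[base]
}

# Watson-Crick pair test for two aligned base vectors.
is_wc_pair <- function(base_a, base_b) {
  unname(complement_base(base_a) == base_b)
}

#' Locate guanine tracts
#'
#' Finds the maximal runs of at least `min_tract_len` consecutive guanines in
#' a sequence; four proximal tracts can fold into a G-quadruplex, and a
#' "split" quadruplex assembles from tracts contributed by the two unpaired
#' overhangs flanking a duplex junction.
#'
#' @param sequence A single DNA sequence.
#' @param min_tract_len Minimum run length (default 3).
#' @return A tibble with columns `start`, `end` (1-based, inclusive), one row
#'   per maximal tract, ordered left to right.
#' @examples
#' find_g_tracts("TGGGTGGGTGGG") # three tracts
#' @export
find_g_tracts <- function(sequence, min_tract_len = 3) {
  stopifnot(length(sequence) == 1, min_tract_len >= 1)
  check_dna(sequence)
  pattern <- sprintf("G{%d,}", min_tract_len)
  loc <- stringr::str_locate_all(sequence, pattern)[[1]]
  tibble::tibble(start = as.integer(loc[, 1]), end = as.integer(loc[, 2]))
}

BASES <- c("A", "C", "G", "T")

# integer base codes 1..4; Watson-Crick partner of code x is 5 - x
seq_to_int <- function(sequence) {
  match(strsplit(sequence, "")[[1]], BASES)
}

#' Enumerate gapless antiparallel duplex windows
#'
#' All contiguous alignments of a window of `seq_a` against a window of
#' `seq_b` (antiparallel, no gaps) with at least `min_len` paired positions
#' and at most `max_mismatches` non-Watson-Crick pairs. Position `a_start + t`
#' of `seq_a` pairs with position `b_end - t` of `seq_b`. G.T wobbles count
#' as mismatches.
#'
#' @param seq_a,seq_b DNA sequences (single strings, 5'->3').
#' @param min_len Minimum number of paired positions (>= 4).
#' @param max_mismatches Maximum number of non-WC pairs in a window.
#' @return A tibble with columns `a_start`, `a_end`, `b_start`, `b_end`
#'   (1-based inclusive), `length`, `mismatches`. Empty if no window
#'   qualifies.
#' @export
duplex_windows <- function(seq_a, seq_b, min_len = 4, max_mismatches = 0) {
  stopifnot(min_len >= 4, max_mismatches >= 0)
  check_dna(c(seq_a, seq_b))
  scored <- duplex_windows_scored(seq_a, seq_b, min_len, max_mismatches,
    params = NULL
  )
  scored[c("a_start", "a_end", "b_start", "b_end", "length", "mismatches")]
}

# Shared window enumeration over antiparallel diagonals (paired index pairs
# (i, j) on diagonal c satisfy i + j = c). When `params` is supplied each
# window also gets its nearest-neighbor free energy (stacks over consecutive
# WC steps + initiation + flat mismatch penalties). Fully vectorized per
# diagonal on integer-coded sequences.
duplex_windows_scored <- function(seq_a, seq_b, min_len, max_mismatches,
                                  params = NULL) {
  ai <- seq_to_int(seq_a)
  bi <- seq_to_int(seq_b)
  n <- length(ai)
  m <- length(bi)
  scored <- !is.null(params)
  acc <- vector("list", n + m - 1L)
  for (c_diag in seq(2L, n + m)) {
    i0 <- max(1L, c_diag - m)
    i1 <- min(n, c_diag - 1L)
    L <- i1 - i0 + 1L
    if (L < min_len) next
    av <- ai[i0:i1]
    bv <- bi[c_diag - (i0:i1)]
    wc <- bv == (5L - av)
    mm_cum <- c(0L, cumsum(!wc))
    nwin <- L - min_len + 1L
    starts <- rep.int(seq_len(nwin), nwin:1L)
    ends <- sequence(nwin:1L, from = seq(min_len, L), by = 1L)
    mm <- mm_cum[ends + 1L] - mm_cum[starts]
    keep <- mm <= max_mismatches
    if (!any(keep)) next
    starts <- starts[keep]
    ends <- ends[keep]
    mm <- mm[keep]
    a_start <- i0 + starts - 1L
    a_end <- i0 + ends - 1L
    row <- list(
      a_start = a_start,
      a_end = a_end,
      b_start = c_diag - a_end,
      b_end = c_diag - a_start,
      length = ends - starts + 1L,
      mismatches = as.integer(mm)
    )
    if (scored) {
      # stack energy of the step between aligned positions t and t+1;
      # only steps flanked by two WC pairs stack
      step_e <- ifelse(
        wc[-L] & wc[-1L],
        params$nn_idx[(av[-L] - 1L) * 4L + av[-1L]],
        0
      )
      e_cum <- c(0, cumsum(step_e))
      term_mm <- as.integer(!wc[starts]) + as.integer(!wc[ends])
      row$dG <- (e_cum[ends] - e_cum[starts]) + params$initiation +
        params$mismatch_internal * (mm - term_mm) +
        params$mismatch_terminal * term_mm
    }
    acc[[c_diag - 1L]] <- row
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  cols <- c(
    "a_start", "a_end", "b_start", "b_end", "length", "mismatches",
    if (scored) "dG"
  )
  if (length(acc) == 0) {
    out <- stats::setNames(
      lapply(cols, function(x) if (x == "dG") numeric(0) else integer(0)),
      cols
    )
    return(tibble::as_tibble(out))
  }
  tibble::as_tibble(stats::setNames(
    lapply(cols, function(col) unlist(lapply(acc, `[[`, col), use.names = FALSE)),
    cols
  ))
}

#' Read a strand set from FASTA
#'
#' Record descriptions carry the role as a `role=` key, e.g.
#' `>MB role=beacon`. Records without a role key default to `"input"`.
#'
#' @param path Path to a FASTA file.
#' @inheritParams strand_set
#' @return A `strand_set` tibble.
#' @export
read_strand_fasta <- function(path, require_beacon = TRUE) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("failed to parse FASTA file '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  headers <- names(seqs)
  name <- stringr::str_trim(stringr::str_remove(headers, "\\s*role=\\S+\\s*$"))
  role_raw <- stringr::str_match(headers, "role=(\\S+)")[, 2]
  role <- ifelse(is.na(role_raw), "input", role_raw)
  tryCatch(
    strand_set(name, as.character(seqs), role, require_beacon = require_beacon),
    error = function(e) {
      stop("invalid strand set in '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
}

#' Write a strand set to FASTA
#'
#' Inverse of [read_strand_fasta()]; the round trip is lossless.
#'
#' @param strands A `strand_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strand_fasta <- function(strands, path) {
  validate_strand_set(strands)
  lines <- character(2L * nrow(strands))
  lines[c(TRUE, FALSE)] <- sprintf(">%s role=%s", strands$name, strands$role)
  lines[c(FALSE, TRUE)] <- strands$sequence
  writeLines(lines, path)
  invisible(path)
}
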