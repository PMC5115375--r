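#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a verification report
#'
#' One row per input combination with expected and simulated digits,
#' channel intensities, threshold margins, and a `pass` flag.
#'
#' @param x An `mb_verification`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mb_verification <- function(x, ...) {
  x$rows
}

#' One-line summary of a verification report
#'
#' @param x An `mb_verification`.
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `n_rows`, `n_pass`, `pass`,
#'   `min_margin` (smallest distance of any channel intensity from the
#'   decoding threshold).
#' @export
glance.mb_verification <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_rows = nrow(x$rows),
    n_pass = x$n_pass,
    pass = x$pass,
    min_margin = min(c(x$rows$fam_margin, x$rows$nmm_margin))
  )
}

#' Tidy a strand design
#'
#' @param x A `strand_design`.
#' @param ... Unused.
#' @return The designed `strand_set` tibble.
#' @export
tidy.strand_design <- function(x, ...) {
  x$strands
}

#' One-line summary of a strand design
#'
#' @param x A `strand_design`.
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `seed`, `n_strands`, `proposals`,
#'   `accepted`, `min_margin` (worst per-row free-energy margin of the
#'   intended matching, kcal/mol).
#' @export
glance.strand_design <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    seed = x$seed,
    n_strands = nrow(x$strands),
    proposals = x$proposals,
    accepted = x$report$accepted,
    min_margin = min(x$report$margins$margin)
  )
}

#' Tidy a design report
#'
#' @param x An `mb_design_report`.
#' @param ... Unused.
#' @return The per-check tibble (`check`, `row`, `ok`, `note`).
#' @export
tidy.mb_design_report <- function(x, ...) {
  x$checks
}

#' One-line summary of a design report
#'
#' @param x An `mb_design_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mb_design_report <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_checks = nrow(x$checks),
    n_violations = x$n_violations,
    accepted = x$accepted,
    min_margin = min(x$margins$margin)
  )
}

#' Tidy a resolved state
#'
#' @param x An `mb_state`.
#' @param ... Unused.
#' @return A tibble of the state's intermolecular duplexes.
#' @export
tidy.mb_state <- function(x, ...) {
  x$duplexes
}

#' One-line summary of a resolved state
#'
#' @param x An `mb_state`.
#' @param ... Unused.
#' @return A one-row tibble: strand/duplex counts, `beacon_open`,
#'   `g4_count`, `total_dG`.
#' @export
glance.mb_state <- function(x, ...) {
  tibble::tibble(
    n_strands = nrow(x$strands),
    n_duplexes = nrow(x$duplexes),
    n_free = length(x$free),
    beacon_closed = !is.null(x$hairpin),
    beacon_open = x$beacon_open,
    g4_count = x$g4_count,
    total_dG = x$total_dG
  )
}
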