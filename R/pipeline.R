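#' Pipeline run configuration
#'
#' Exactly one of `strand_path` (a FASTA strand set) or `design_seed` (design
#' a fresh set) must be given. All randomness in a run flows from the single
#' seed; module-level seeds are derived from it deterministically.
#'
#' @param kind Circuit kind.
#' @param strand_path Optional FASTA file with the strand set.
#' @param design_seed Optional integer seed for [design_strands()].
#' @param out_dir Output directory (created if needed).
#' @param params_path Optional thermodynamic parameter file.
#' @param decode A [decode_config()].
#' @param noise Optional [noise_config()] for fixture output.
#' @param constraints A [design_constraints()].
#' @param verbose Log progress to standard error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(kind, strand_path = NULL, design_seed = NULL,
                       out_dir = tempfile("mblogic_run_"),
                       params_path = NULL,
                       decode = decode_config(), noise = NULL,
                       constraints = design_constraints(), verbose = TRUE) {
  kind <- match.arg(kind, circuit_kinds)
  if (is.null(strand_path) == is.null(design_seed)) {
    stop("exactly one of strand_path or design_seed is required", call. = FALSE)
  }
  structure(
    list(
      kind = kind, strand_path = strand_path, design_seed = design_seed,
      out_dir = out_dir, params_path = params_path, decode = decode,
      noise = noise, constraints = constraints, verbose = verbose
    ),
    class = "run_config"
  )
}

pipeline_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[mblogic] ", ...)
}

#' Run the design-simulate-verify pipeline
#'
#' Designs (or loads) a strand set for the requested circuit, simulates its
#' full truth table, verifies it against the electronic reference, and
#' writes the artifacts to disk: the strand FASTA, the truth-table TSV, the
#' verification report JSON, and (when a noise configuration is given) a
#' noisy readout fixture TSV. Logs go to standard error; data go to files;
#' outputs carry no timestamps, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `strands`, `truth_table`, `verification`,
#'   `design` (or `NULL`), and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  params <- thermo_params(config$params_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- NULL
  if (!is.null(config$design_seed)) {
    pipeline_log(config, "designing ", config$kind, " strand set (seed ",
      config$design_seed, ")")
    design <- design_strands(config$kind, config$design_seed,
      constraints = config$constraints, params = params
    )
    strands <- design$strands
    pipeline_log(config, "design accepted after ", design$proposals,
      " proposal(s)")
  } else {
    pipeline_log(config, "reading strand set from ", config$strand_path)
    strands <- read_strand_fasta(config$strand_path)
  }
  circuit <- circuit_def(config$kind)
  missing <- setdiff(circuit$input_names, strands$name)
  if (length(missing) > 0) {
    stop(
      "strand set", if (!is.null(config$strand_path)) {
        paste0(" in '", config$strand_path, "'")
      } else {
        ""
      },
      " is missing circuit input(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  pipeline_log(config, "simulating truth table")
  verification <- verify_circuit(circuit, strands, params,
    decode = config$decode
  )
  files <- list(
    fasta = file.path(config$out_dir, "strands.fasta"),
    truth_table = file.path(config$out_dir, "truth_table.tsv"),
    verification = file.path(config$out_dir, "verification.json")
  )
  write_strand_fasta(strands, files$fasta)
  write_truth_table_tsv(verification$truth_table, files$truth_table)
  report <- list(
    kind = config$kind,
    pass = verification$pass,
    n_pass = verification$n_pass,
    n_rows = nrow(verification$rows),
    rows = verification$rows
  )
  if (!is.null(design)) {
    report$design <- list(
      seed = design$seed,
      proposals = design$proposals,
      accepted = design$report$accepted,
      margins = design$report$margins
    )
  }
  jsonlite::write_json(report, files$verification,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(config$noise)) {
    files$fixture <- file.path(config$out_dir, "fixture.tsv")
    fix_seed <- if (!is.null(config$design_seed)) config$design_seed + 1L else 1L
    fixture <- generate_fixture(strands,
      kind = config$kind, seed = fix_seed,
      noise = config$noise, params = params
    )
    utils::write.table(fixture, files$fixture,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  pipeline_log(
    config, "verification ", if (verification$pass) "PASS" else "FAIL",
    " (", verification$n_pass, "/", nrow(verification$rows), " rows)"
  )
  invisible(list(
    strands = strands, truth_table = verification$truth_table,
    verification = verification, design = design, files = files
  ))
}

#' Write a simulated truth table as TSV
#'
#' @param truth_table An `mb_truth_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table_tsv <- function(truth_table, path) {
  utils::write.table(
    as.data.frame(truth_table), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a truth-table TSV written by [write_truth_table_tsv()]
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_truth_table_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  ))
}
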