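#' Design constraints for circuit strand sets
#'
#' Geometry and energy constraints the designer must satisfy. Defaults encode
#' the platform's design rules: a hairpin beacon every input can open; a
#' single-base mismatch embedded in every beacon-input duplex of a two-input
#' circuit and a two-base mismatch for three-input circuits (the mismatch
#' strategy that weakens beacon-input duplexes so that fully complementary
#' input-input hybridization takes priority); guanine-tract payloads placed
#' next to the intended duplex junctions (including the literal half-adder
#' split segments `GGGT` / `TGGGTGGGTGGG`); and a crosstalk cap forbidding
#' unintended near-complementary windows.
#'
#' @param stem_len Beacon stem length, bp (default 6).
#' @param loop_len Beacon loop length, nt (default 20).
#' @param mb_site_len Length of each input's beacon-binding site (default 16).
#' @param block_len Input-input complementary block length for two-input
#'   circuits and the non-dominant full-adder pairs (default 18).
#' @param dominant_block_len Block length of the full-adder pair designed to
#'   dominate the three-input row (default 24).
#' @param fs_block_len Block length of the dominant full-subtractor pair
#'   (default 34; it must also out-compete the long cassette-covering
#'   duplexes).
#' @param anchor_len Perfect base pairs the cassette-covering strand grabs
#'   beyond the cassette itself (default 6).
#' @param spacer_len Spacer between the half-subtractor input's beacon site
#'   and its cassette (default 8).
#' @param crosstalk_len,crosstalk_mismatches No unintended duplex window of
#'   at least `crosstalk_len` paired positions with at most
#'   `crosstalk_mismatches` mismatches may exist (defaults 12 and 1; short
#'   chance complementarities below this size are energetically irrelevant
#'   next to the designed blocks and are additionally dominated away by the
#'   free-energy margin check).
#' @param margin Minimum free-energy separation (kcal/mol) between the
#'   intended matching and the best alternative in every row (default 2).
#' @param max_proposals Proposals before the search gives up (default 10000).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(stem_len = 6, loop_len = 20, mb_site_len = 16,
                               block_len = 18, dominant_block_len = 24,
                               fs_block_len = 34, anchor_len = 6,
                               spacer_len = 8,
                               crosstalk_len = 12, crosstalk_mismatches = 1,
                               margin = 2, max_proposals = 10000) {
  stopifnot(
    stem_len >= 3, loop_len >= 6, mb_site_len >= 8,
    mb_site_len <= loop_len - 2, block_len >= 8, margin > 0
  )
  structure(
    list(
      stem_len = stem_len, loop_len = loop_len, mb_site_len = mb_site_len,
      block_len = block_len, dominant_block_len = dominant_block_len,
      fs_block_len = fs_block_len, anchor_len = anchor_len,
      spacer_len = spacer_len,
      crosstalk_len = crosstalk_len,
      crosstalk_mismatches = crosstalk_mismatches,
      margin = margin, max_proposals = max_proposals
    ),
    class = "design_constraints"
  )
}

# G-tract cassettes: four (intramolecular) or three/one (split) G3 tracts.
CASSETTE_T <- "GGGTGGGTGGGTGGG" # 4 tracts, T spacers
CASSETTE_A <- "GGGAGGGAGGGAGGG" # 4 tracts, A spacers
SPLIT_3 <- "TGGGTGGGTGGG" # 3 tracts (half-adder 3' split segment)
SPLIT_1_5P <- "GGGT" # 1 tract  (half-adder 5' split segment)
SPLIT_1_3P <- "TGGG"

mismatch_k <- function(kind) {
  if (n_inputs(kind) == 3L) 2L else 1L
}

# Random sequence over {A, C, T}; rejects CCC runs so that neither the
# region nor its complement can seed a guanine tract. Optional boundary
# constraints keep a block's complement from starting/ending in G, which
# would otherwise merge with a G-tract payload abutting it on the partner
# strand and drag the tract into the paired region.
sample_act <- function(n, first_not = NULL, last_not = NULL) {
  repeat {
    s <- paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
    if (grepl("CCC", s)) next
    if (!is.null(first_not) && substr(s, 1, 1) %in% first_not) next
    if (!is.null(last_not) && substr(s, n, n) %in% last_not) next
    return(s)
  }
}

sample_stem <- function(n) {
  repeat {
    s <- paste(
      sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = c(1, 2, 2, 1)),
      collapse = ""
    )
    if (!grepl("GGG", s) && !grepl("CCC", s)) {
      return(s)
    }
  }
}

# Beacon-binding site: reverse complement of a loop window with k central
# mismatching substitutions (internal, never terminal).
make_mb_site <- function(loop_seq, site_len, k) {
  loop_sub <- substr(loop_seq, 3, 2 + site_len)
  site <- strsplit(reverse_complement(loop_sub), "")[[1]]
  pos <- if (k == 1L) {
    round(site_len / 2)
  } else {
    round(site_len * c(1 / 3, 2 / 3))
  }
  for (p in pos) {
    choices <- setdiff(c("A", "C", "T"), site[p])
    site[p] <- sample(choices, 1)
  }
  paste(site, collapse = "")
}

propose_strand_set <- function(kind, constraints, params) {
  cns <- constraints
  # stem must close into a clearly stable hairpin
  repeat {
    stem <- sample_stem(cns$stem_len)
    mb <- paste0(stem, sample_act(cns$loop_len), reverse_complement(stem))
    hp <- best_hairpin(mb, params)
    if (!is.null(hp) && hp$dG < -2) break
  }
  loop <- substr(mb, cns$stem_len + 1L, cns$stem_len + cns$loop_len)
  site <- make_mb_site(loop, cns$mb_site_len, mismatch_k(kind))
  inputs <- circuit_def(kind)$input_names
  seqs <- switch(kind,
    half_adder = {
      blk <- sample_act(cns$block_len)
      list(
        paste0(SPLIT_1_5P, blk, site),
        paste0(site, reverse_complement(blk), SPLIT_3)
      )
    },
    half_subtractor = ,
    comparator = {
      spacer <- sample_act(cns$spacer_len)
      in2 <- paste0(site, spacer, CASSETTE_T)
      in1 <- paste0(site, reverse_complement(paste0(spacer, CASSETTE_T)))
      list(in1, in2)
    },
    full_adder = {
      b12 <- sample_act(cns$block_len)
      b13 <- sample_act(cns$block_len, last_not = "C")
      b23 <- sample_act(cns$dominant_block_len, last_not = "C")
      list(
        paste0(SPLIT_1_5P, b12, site, b13, SPLIT_1_3P),
        paste0(site, reverse_complement(b12), SPLIT_3, b23, SPLIT_3),
        paste0(
          SPLIT_3, reverse_complement(b13), SPLIT_3,
          reverse_complement(b23), site
        )
      )
    },
    full_subtractor = {
      b23 <- sample_act(cns$fs_block_len, first_not = "C")
      in2 <- paste0(site, b23, CASSETTE_T)
      in3 <- paste0(site, reverse_complement(b23), CASSETTE_A)
      grab <- function(s) {
        n <- nchar(s)
        reverse_complement(substr(s, n - 15 + 1 - cns$anchor_len, n))
      }
      in1 <- paste0(site, grab(in2), grab(in3))
      list(in1, in2, in3)
    }
  )
  strand_set(
    name = c("MB", inputs),
    sequence = c(mb, unlist(seqs)),
    role = c("beacon", rep("input", length(inputs)))
  )
}

# Intended behavior of every input combination: which duplexes form, whether
# the beacon opens, and how many G-quadruplexes assemble.
intended_plan <- function(kind) {
  inputs <- circuit_def(kind)$input_names
  bits <- input_grid(length(inputs))
  n <- nrow(bits)
  pair <- function(i, j) list(sort(c(inputs[i], inputs[j])))
  mb_pair <- function(i) list(sort(c("MB", inputs[i])))
  plan <- vector("list", n)
  for (r in seq_len(n)) {
    b <- unlist(bits[r, ])
    on <- unname(which(b == 1L))
    if (kind %in% c("half_adder", "half_subtractor", "comparator")) {
      plan[[r]] <- switch(as.character(length(on)),
        "0" = list(edges = list(), open = FALSE, g4 = 0L),
        "1" = list(
          edges = mb_pair(on), open = TRUE,
          g4 = if (kind != "half_adder" && on == 2L) 1L else 0L
        ),
        "2" = list(
          edges = pair(1, 2), open = FALSE,
          g4 = if (kind == "half_adder") 1L else 0L
        )
      )
    } else if (kind == "full_adder") {
      plan[[r]] <- switch(as.character(length(on)),
        "0" = list(edges = list(), open = FALSE, g4 = 0L),
        "1" = list(edges = mb_pair(on), open = TRUE, g4 = 0L),
        "2" = list(edges = pair(on[1], on[2]), open = FALSE, g4 = 1L),
        "3" = list(
          edges = c(pair(2, 3), mb_pair(1)), open = TRUE, g4 = 1L
        )
      )
    } else { # full_subtractor
      plan[[r]] <- switch(as.character(length(on)),
        "0" = list(edges = list(), open = FALSE, g4 = 0L),
        "1" = list(
          edges = mb_pair(on), open = TRUE,
          g4 = if (on == 1L) 0L else 1L
        ),
        "2" = list(
          edges = pair(on[1], on[2]), open = FALSE,
          g4 = if (identical(on, c(2L, 3L))) 2L else 0L
        ),
        "3" = list(
          edges = c(pair(2, 3), mb_pair(1)), open = TRUE, g4 = 2L
        )
      )
    }
  }
  list(bits = bits, plan = plan, inputs = inputs)
}

# Total free energy of every matching of the strand subset, keyed by the
# canonical sorted-pair-name key.
matching_totals <- function(strands, params, search) {
  cand <- enumerate_candidates(strands, params, search)
  dup <- cand[cand$type == "duplex", ]
  hp <- cand[cand$type == "hairpin", ]
  hairpin_dG <- if (nrow(hp) == 1) hp$dG else 0
  bname <- beacon_name(strands)
  nm <- strands$name
  res <- list()
  rec <- function(left, cost, edges) {
    if (length(left) == 0) {
      res[[length(res) + 1L]] <<- list(key = matching_key(edges), total = cost)
      return(invisible(NULL))
    }
    first <- left[1]
    solo <- if (!is.na(bname) && first == bname) hairpin_dG else 0
    rec(left[-1], cost + solo, edges)
    for (partner in left[-1]) {
      hit <- dup[(dup$strand_a == first & dup$strand_b == partner) |
        (dup$strand_b == first & dup$strand_a == partner), ]
      if (nrow(hit) == 0) next
      rec(
        setdiff(left[-1], partner), cost + hit$dG[1],
        c(edges, list(c(first, partner)))
      )
    }
    invisible(NULL)
  }
  rec(nm, 0, list())
  tibble::tibble(
    key = vapply(res, `[[`, character(1), "key"),
    total = vapply(res, `[[`, numeric(1), "total")
  )
}

#' Check a strand set against a circuit's design constraints
#'
#' Verifies, for every input combination, that (a) the intended matching is
#' the exhaustive free-energy optimum and beats every alternative by at
#' least the configured margin, (b) the beacon opens exactly in the intended
#' rows, (c) the G-quadruplex count matches the intended per-row plan
#' (including the two-count rows of the full subtractor), (d) no unintended
#' near-complementary window violates the crosstalk cap, and (e) each
#' beacon-input duplex carries exactly the prescribed number of mismatches.
#'
#' @param kind Circuit kind.
#' @param strands A `strand_set` with the beacon and all circuit inputs.
#' @param constraints A [design_constraints()].
#' @param params A `thermo_params` object.
#' @param search A [search_config()].
#' @param g4 A [g4_config()].
#' @return An object of class `mb_design_report`: tibble of `checks`
#'   (check, row label, ok, note), `margins` per row, and `accepted`
#'   (zero violations).
#' @export
check_design <- function(kind, strands, constraints = design_constraints(),
                         params = thermo_params(),
                         search = search_config(), g4 = g4_config()) {
  kind <- match.arg(kind, circuit_kinds)
  ip <- intended_plan(kind)
  checks <- list()
  margins <- numeric(nrow(ip$bits))
  add <- function(check, row, ok, note = "") {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, row = row, ok = ok, note = note
    )
  }
  for (r in seq_len(nrow(ip$bits))) {
    b <- unlist(ip$bits[r, ])
    label <- paste(b, collapse = "")
    present <- ip$inputs[b == 1L]
    sub <- subset_strands(strands, present)
    plan <- ip$plan[[r]]
    state <- brute_force_state(sub, params, search, g4)
    found_key <- matching_key(
      purrr::map(
        seq_len(nrow(state$duplexes)),
        ~ c(state$duplexes$strand_a[.x], state$duplexes$strand_b[.x])
      )
    )
    intended_key <- matching_key(plan$edges)
    add(
      "optimal_matching", label, found_key == intended_key,
      if (found_key != intended_key) "optimum differs from intended" else ""
    )
    totals <- matching_totals(sub, params, search)
    intended_total <- totals$total[totals$key == intended_key]
    others <- totals$total[totals$key != intended_key]
    margins[r] <- if (length(intended_total) == 0) {
      -Inf
    } else if (length(others) == 0) {
      Inf
    } else {
      min(others) - intended_total[1]
    }
    add(
      "energy_margin", label,
      margins[r] >= constraints$margin,
      sprintf("margin %.2f kcal/mol", margins[r])
    )
    add(
      "beacon_open", label, identical(state$beacon_open, plan$open),
      sprintf("open=%s intended=%s", state$beacon_open, plan$open)
    )
    add(
      "g4_count", label, identical(state$g4_count, plan$g4),
      sprintf("count=%d intended=%d", state$g4_count, plan$g4)
    )
  }
  # (d) crosstalk: every near-complementary window must lie on an intended
  # interaction region
  full_state_edges <- unique(unlist(
    purrr::map(ip$plan, "edges"),
    recursive = FALSE
  ))
  intended_windows <- purrr::map(full_state_edges, function(e) {
    seq_a <- strands$sequence[strands$name == e[1]]
    seq_b <- strands$sequence[strands$name == e[2]]
    bd <- best_duplex(seq_a, seq_b, params, search)
    list(pair = e, window = if (is.null(bd)) NULL else bd$window)
  })
  nm <- strands$name
  ok_xtalk <- TRUE
  note_xtalk <- ""
  for (i in seq_len(length(nm) - 1L)) {
    for (j in seq(i + 1L, length(nm))) {
      pair <- sort(c(nm[i], nm[j]))
      # scan in sorted-pair orientation so coordinates align with the
      # intended windows below
      wins <- duplex_windows(
        strands$sequence[strands$name == pair[1]],
        strands$sequence[strands$name == pair[2]],
        min_len = constraints$crosstalk_len,
        max_mismatches = constraints$crosstalk_mismatches
      )
      if (nrow(wins) == 0) next
      iw <- purrr::detect(intended_windows, ~ identical(.x$pair, pair))
      if (is.null(iw) || is.null(iw$window)) {
        ok_xtalk <- FALSE
        note_xtalk <- paste0("unintended windows between ", nm[i], " and ", nm[j])
        next
      }
      # allow windows overlapping the intended region on both strands
      ov <- wins$a_start <= iw$window$a_end & wins$a_end >= iw$window$a_start &
        wins$b_start <= iw$window$b_end & wins$b_end >= iw$window$b_start
      if (!all(ov)) {
        ok_xtalk <- FALSE
        note_xtalk <- paste0("crosstalk window between ", nm[i], " and ", nm[j])
      }
    }
  }
  add("crosstalk", "all", ok_xtalk, note_xtalk)
  # (e) beacon-input mismatch counts
  k <- mismatch_k(kind)
  mb_seq <- strands$sequence[strands$role == "beacon"]
  for (input in ip$inputs) {
    in_seq <- strands$sequence[strands$name == input]
    bd <- best_duplex(mb_seq, in_seq, params, search)
    ok <- !is.null(bd) && bd$window$mismatches == k
    add(
      "mb_mismatches", input, ok,
      if (is.null(bd)) {
        "no beacon duplex"
      } else {
        sprintf("mismatches=%d required=%d", bd$window$mismatches, k)
      }
    )
  }
  checks <- dplyr::bind_rows(checks)
  structure(
    list(
      kind = kind,
      checks = checks,
      margins = tibble::tibble(
        row = apply(ip$bits, 1, paste, collapse = ""),
        margin = margins
      ),
      n_violations = sum(!checks$ok),
      accepted = all(checks$ok)
    ),
    class = "mb_design_report"
  )
}

#' Design a strand set realizing a circuit
#'
#' Seeded propose-and-check search: each proposal instantiates the circuit's
#' strand template (hairpin beacon, shared mismatched beacon-binding site,
#' complementary blocks, G-tract payloads at the intended junctions) with
#' fresh random sequence in the non-structural regions, then runs
#' [check_design()]; the first proposal with zero violations is returned.
#' Deterministic for a given seed.
#'
#' @param kind Circuit kind.
#' @param seed Integer seed driving all proposal randomness.
#' @param constraints A [design_constraints()].
#' @param params A `thermo_params` object.
#' @param search A [search_config()].
#' @param g4 A [g4_config()].
#' @return An object of class `strand_design`: `strands` (the accepted
#'   `strand_set`), `report` (its [check_design()] report), `kind`, `seed`,
#'   `proposals` tried, and `constraints`.
#' @examples
#' \donttest{
#' des <- design_strands("half_adder", seed = 1)
#' des$strands
#' }
#' @export
design_strands <- function(kind, seed, constraints = design_constraints(),
                           params = thermo_params(),
                           search = search_config(), g4 = g4_config()) {
  kind <- match.arg(kind, circuit_kinds)
  set.seed(seed)
  closest <- NULL
  for (i in seq_len(constraints$max_proposals)) {
    strands <- propose_strand_set(kind, constraints, params)
    report <- check_design(kind, strands, constraints, params, search, g4)
    if (report$accepted) {
      return(structure(
        list(
          strands = strands, report = report, kind = kind, seed = seed,
          proposals = i, constraints = constraints
        ),
        class = "strand_design"
      ))
    }
    if (is.null(closest) || report$n_violations < closest$report$n_violations) {
      closest <- list(strands = strands, report = report)
    }
  }
  stop(
    "design search failed after ", constraints$max_proposals,
    " proposals; closest candidate had ", closest$report$n_violations,
    " violation(s): ",
    paste(
      utils::head(closest$report$checks$note[!closest$report$checks$ok], 3),
      collapse = "; "
    ),
    call. = FALSE
  )
}

#' @export
print.strand_design <- function(x, ...) {
  cat(
    "<strand_design>", x$kind, "seed", x$seed,
    "-", nrow(x$strands), "strands,",
    x$proposals, "proposal(s),",
    if (x$report$accepted) "accepted" else "rejected", "\n"
  )
  print(x$strands, ...)
  invisible(x)
}

#' @export
print.mb_design_report <- function(x, ...) {
  cat(
    "<mb_design_report>", x$kind, "-",
    x$n_violations, "violation(s);",
    if (x$accepted) "accepted" else "rejected", "\n"
  )
  bad <- x$checks[!x$checks$ok, ]
  if (nrow(bad) > 0) print(bad, ...)
  invisible(x)
}

#' Generate a synthetic readout fixture
#'
#' Emulates the normalized dual-channel readout of a designed circuit: for
#' every input combination, the noiseless intensities (closed-beacon leak
#' included) plus seeded noisy replicates. The statistical structure mirrors
#' experimental normalized intensities - off-states at the leak level, on
#' states at 1 (or 2 for two G-quadruplex equivalents) - without modelling
#' spectra or kinetics.
#'
#' @param design A `strand_design` (or a `strand_set` plus `kind`).
#' @param kind Circuit kind; taken from `design` when omitted.
#' @param seed Seed for the noise stream.
#' @param noise A [noise_config()].
#' @param replicates Noisy replicates per combination (default 3).
#' @param params,search,g4 Model configuration.
#' @return A tibble: input bits, `replicate` (0 = noiseless), `fam_norm`,
#'   `nmm_norm`.
#' @export
generate_fixture <- function(design, kind = NULL, seed = 1,
                             noise = noise_config(), replicates = 3,
                             params = thermo_params(),
                             search = search_config(), g4 = g4_config()) {
  if (inherits(design, "strand_design")) {
    strands <- design$strands
    kind <- design$kind
  } else {
    strands <- design
    if (is.null(kind)) stop("kind must be given with a bare strand set", call. = FALSE)
  }
  circuit <- circuit_def(kind)
  bits <- input_grid(length(circuit$input_names))
  set.seed(seed)
  quiet <- noise_config(noise$fam_leak, 0)
  rows <- purrr::map(seq_len(nrow(bits)), function(i) {
    present <- circuit$input_names[unlist(bits[i, ]) == 1L]
    state <- resolve_state(subset_strands(strands, present), params, search, g4)
    base <- channel_intensities(state, quiet)
    reps <- purrr::map(seq_len(replicates), function(rep) {
      noisy <- channel_intensities(state, noise)
      tibble::tibble(
        replicate = rep,
        fam_norm = noisy$fam_norm, nmm_norm = noisy$nmm_norm
      )
    })
    out <- dplyr::bind_rows(
      tibble::tibble(
        replicate = 0L,
        fam_norm = base$fam_norm, nmm_norm = base$nmm_norm
      ),
      dplyr::bind_rows(reps)
    )
    dplyr::bind_cols(bits[rep(i, nrow(out)), ], out)
  })
  dplyr::bind_rows(rows)
}
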