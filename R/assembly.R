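#' G-quadruplex detection configuration
#'
#' A G-quadruplex needs four guanine tracts. Two geometries are scored on a
#' resolved state: a *split* quadruplex assembled at a duplex junction from
#' tracts on the two unpaired overhangs flanking that junction, and an
#' *intramolecular* quadruplex folded by four tracts lying close together in
#' a single unpaired region. Hybridized (paired) positions never contribute -
#' hybridization sequesters tracts - and each tract folds into at most one
#' quadruplex.
#'
#' @param min_tract_len Minimum guanine run length (default 3).
#' @param tracts_required Tracts needed per quadruplex (default 4).
#' @param junction_window Maximum distance (nt) from a duplex junction at
#'   which an overhang tract can still join a split quadruplex (default 15).
#' @param intramol_span Maximum span (nt) of four tracts folding into an
#'   intramolecular quadruplex (default 30).
#' @return A list of class `g4_config`.
#' @export
g4_config <- function(min_tract_len = 3, tracts_required = 4,
                      junction_window = 15, intramol_span = 30) {
  stopifnot(min_tract_len >= 1, tracts_required >= 1, junction_window >= 0)
  structure(
    list(
      min_tract_len = as.integer(min_tract_len),
      tracts_required = as.integer(tracts_required),
      junction_window = as.integer(junction_window),
      intramol_span = as.integer(intramol_span)
    ),
    class = "g4_config"
  )
}

#' Enumerate duplex candidates for a strand set
#'
#' The best duplex for every unordered pair of strands (including
#' beacon-input pairs), plus the beacon's closed-hairpin self-candidate.
#' These candidates form the competition graph on which
#' [resolve_state()] finds the minimum-free-energy matching.
#'
#' @param strands A `strand_set`.
#' @param params A `thermo_params` object.
#' @param search A [search_config()].
#' @return A tibble with columns `strand_a`, `strand_b`, `type`
#'   (`"duplex"` or `"hairpin"`), window coordinates, `length`,
#'   `mismatches`, `stem_len`, `dG`.
#' @export
enumerate_candidates <- function(strands, params = thermo_params(), search = search_config()) {
  validate_strand_set(strands, require_beacon = FALSE)
  seqs <- stats::setNames(strands$sequence, strands$name)
  n <- nrow(strands)
  rows <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        bd <- best_duplex(seqs[[i]], seqs[[j]], params, search)
        if (is.null(bd)) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strand_a = strands$name[i], strand_b = strands$name[j],
          type = "duplex",
          a_start = bd$window$a_start, a_end = bd$window$a_end,
          b_start = bd$window$b_start, b_end = bd$window$b_end,
          length = bd$window$length, mismatches = bd$window$mismatches,
          stem_len = NA_integer_, dG = bd$dG
        )
      }
    }
  }
  bname <- beacon_name(strands)
  if (!is.na(bname)) {
    hp <- best_hairpin(seqs[[bname]], params)
    if (!is.null(hp)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strand_a = bname, strand_b = bname, type = "hairpin",
        a_start = NA_integer_, a_end = NA_integer_,
        b_start = NA_integer_, b_end = NA_integer_,
        length = hp$stem_len, mismatches = 0L,
        stem_len = hp$stem_len, dG = hp$dG
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      strand_a = character(), strand_b = character(), type = character(),
      a_start = integer(), a_end = integer(), b_start = integer(),
      b_end = integer(), length = integer(), mismatches = integer(),
      stem_len = integer(), dG = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

# Canonical comparison key of a matching: sorted "a|b" pair names. Matchings
# with equal total free energy are resolved toward the lexicographically
# smallest key, making resolved states deterministic.
matching_key <- function(edges) {
  if (length(edges) == 0) {
    return("")
  }
  keys <- vapply(
    edges,
    function(e) paste(sort(e), collapse = "\x1f"),
    character(1)
  )
  paste(sort(keys), collapse = "\x1e")
}

# Assemble an mb_state from a chosen set of intermolecular edges.
build_state <- function(strands, edges, params, search, g4, open_margin = 0) {
  seqs <- stats::setNames(strands$sequence, strands$name)
  bname <- beacon_name(strands)
  duplexes <- list()
  matched <- character(0)
  for (e in edges) {
    a <- e[1]
    b <- e[2]
    bd <- best_duplex(seqs[[a]], seqs[[b]], params, search)
    stopifnot(!is.null(bd))
    duplexes[[length(duplexes) + 1L]] <- tibble::tibble(
      strand_a = a, strand_b = b,
      a_start = bd$window$a_start, a_end = bd$window$a_end,
      b_start = bd$window$b_start, b_end = bd$window$b_end,
      length = bd$window$length, mismatches = bd$window$mismatches,
      dG = bd$dG
    )
    matched <- c(matched, a, b)
  }
  duplexes <- if (length(duplexes)) {
    dplyr::bind_rows(duplexes)
  } else {
    tibble::tibble(
      strand_a = character(), strand_b = character(), a_start = integer(),
      a_end = integer(), b_start = integer(), b_end = integer(),
      length = integer(), mismatches = integer(), dG = numeric()
    )
  }
  hairpin <- NULL
  beacon_matched <- !is.na(bname) && bname %in% matched
  if (!is.na(bname) && !beacon_matched) {
    hp <- best_hairpin(seqs[[bname]], params)
    if (!is.null(hp)) hairpin <- hp
  }
  hairpin_dG <- if (is.null(hairpin)) 0 else hairpin$dG
  total_dG <- sum(duplexes$dG) + if (!is.na(bname) && !beacon_matched) hairpin_dG else 0
  beacon_open <- FALSE
  if (beacon_matched) {
    hp_ref <- best_hairpin(seqs[[bname]], params)
    hp_dg <- if (is.null(hp_ref)) 0 else hp_ref$dG
    mb_dup <- duplexes[duplexes$strand_a == bname | duplexes$strand_b == bname, ]
    beacon_open <- mb_dup$dG[1] < hp_dg - open_margin
  }
  state <- structure(
    list(
      strands = strands,
      duplexes = duplexes,
      hairpin = hairpin,
      free = setdiff(strands$name, c(matched, if (!is.null(hairpin)) bname)),
      beacon = bname,
      beacon_open = beacon_open,
      total_dG = total_dG,
      g4_count = NA_integer_,
      g4_config = g4
    ),
    class = "mb_state"
  )
  g4_res <- count_g_quadruplexes(state, g4, detail = TRUE)
  state$g4_count <- g4_res$count
  state$g4_detail <- g4_res$detail
  state
}

#' Resolve the equilibrium complexes for one input combination
#'
#' Winner-take-all discrete equilibrium: each strand joins at most one
#' intermolecular duplex, an unmatched beacon folds back into its hairpin,
#' unmatched inputs stay free, and the chosen matching minimizes the total
#' free energy over all alternatives. This is the in-silico counterpart of
#' the design principle that the strongest hybridization (e.g. a fully
#' complementary input-input duplex) takes priority over weaker,
#' mismatch-containing beacon-input duplexes. Exact search with
#' branch-and-bound over the candidate graph; ties are broken by the
#' lexicographically smallest sorted pair-name key.
#'
#' @inheritParams enumerate_candidates
#' @param g4 A [g4_config()].
#' @param open_margin The beacon counts as open only when its duplex is at
#'   least this much (kcal/mol) more stable than its hairpin (default 0).
#' @return An `mb_state` object: chosen `duplexes`, `hairpin`, `free`
#'   strands, `beacon_open`, `total_dG` and `g4_count`.
#' @export
resolve_state <- function(strands, params = thermo_params(), search = search_config(),
                          g4 = g4_config(), open_margin = 0) {
  validate_strand_set(strands, require_beacon = FALSE)
  cand <- enumerate_candidates(strands, params, search)
  nm <- strands$name
  n <- length(nm)
  bname <- beacon_name(strands)
  hairpin_dG <- 0
  hp <- cand[cand$type == "hairpin", ]
  if (nrow(hp) == 1) hairpin_dG <- hp$dG
  dup <- cand[cand$type == "duplex", ]
  # incident candidate edges per strand index
  edge_dg <- function(a, b) {
    hit <- dup[(dup$strand_a == a & dup$strand_b == b) |
      (dup$strand_a == b & dup$strand_b == a), ]
    if (nrow(hit) == 0) NULL else hit$dG[1]
  }
  best <- list(cost = Inf, key = NULL, edges = list())
  consider <- function(cost, edges) {
    key <- matching_key(edges)
    if (cost < best$cost - 1e-9 ||
      (abs(cost - best$cost) <= 1e-9 && key < best$key)) {
      best <<- list(cost = cost, key = key, edges = edges)
    }
  }
  # cost of leaving strand k unmatched
  solo_cost <- function(k) {
    if (!is.na(bname) && nm[k] == bname) hairpin_dG else 0
  }
  rec <- function(assigned, cost, edges) {
    k <- which(!assigned)[1]
    if (is.na(k)) {
      consider(cost, edges)
      return(invisible(NULL))
    }
    # lower bound: every remaining strand at best contributes half its most
    # stable incident edge (or its solo cost)
    remaining <- which(!assigned)
    lb <- sum(vapply(remaining, function(u) {
      inc <- dup$dG[(dup$strand_a == nm[u] & dup$strand_b %in% nm[remaining]) |
        (dup$strand_b == nm[u] & dup$strand_a %in% nm[remaining])]
      min(solo_cost(u), if (length(inc)) min(inc) / 2 else 0)
    }, numeric(1)))
    if (cost + lb > best$cost + 1e-9) {
      return(invisible(NULL))
    }
    # option 1: strand k stays single (hairpin if beacon, free otherwise)
    assigned[k] <- TRUE
    rec(assigned, cost + solo_cost(k), edges)
    # option 2: pair with a later unassigned strand
    for (l in which(!assigned)) {
      dg <- edge_dg(nm[k], nm[l])
      if (is.null(dg)) next
      assigned[l] <- TRUE
      rec(assigned, cost + dg, c(edges, list(c(nm[k], nm[l]))))
      assigned[l] <- FALSE
    }
    invisible(NULL)
  }
  if (n > 0) rec(rep(FALSE, n), 0, list()) else consider(0, list())
  build_state(strands, best$edges, params, search, g4, open_margin)
}

#' Exhaustive reference resolver (test oracle)
#'
#' Enumerates every matching of the strand set explicitly, scores each from
#' scratch, and returns the global minimum-free-energy state under the same
#' tie-break as [resolve_state()]. Exponential; limited to 7 strands.
#'
#' @inheritParams resolve_state
#' @return An `mb_state` object.
#' @export
brute_force_state <- function(strands, params = thermo_params(), search = search_config(),
                              g4 = g4_config(), open_margin = 0) {
  validate_strand_set(strands, require_beacon = FALSE)
  if (nrow(strands) > 7) {
    stop("brute_force_state is limited to 7 strands", call. = FALSE)
  }
  nm <- strands$name
  seqs <- stats::setNames(strands$sequence, strands$name)
  bname <- beacon_name(strands)
  hp <- if (!is.na(bname)) best_hairpin(seqs[[bname]], params) else NULL
  hairpin_dG <- if (is.null(hp)) 0 else hp$dG

  # all matchings (involutions) of the name vector
  all_matchings <- function(names_left) {
    if (length(names_left) <= 1) {
      return(list(list()))
    }
    first <- names_left[1]
    rest <- names_left[-1]
    out <- lapply(all_matchings(rest), identity) # first stays single
    for (partner in rest) {
      sub <- all_matchings(setdiff(rest, partner))
      out <- c(out, lapply(sub, function(m) c(m, list(c(first, partner)))))
    }
    out
  }
  matchings <- all_matchings(nm)
  score <- function(edges) {
    total <- 0
    for (e in edges) {
      bd <- best_duplex(seqs[[e[1]]], seqs[[e[2]]], params, search)
      if (is.null(bd)) {
        return(NA_real_)
      }
      total <- total + bd$dG
    }
    matched <- unlist(edges)
    if (!is.na(bname) && !(bname %in% matched)) total <- total + hairpin_dG
    total
  }
  totals <- vapply(matchings, score, numeric(1))
  keys <- vapply(matchings, matching_key, character(1))
  ok <- !is.na(totals)
  matchings <- matchings[ok]
  totals <- totals[ok]
  keys <- keys[ok]
  near <- totals <= min(totals) + 1e-9
  pick <- which(near)[order(keys[near])][1]
  build_state(strands, matchings[[pick]], params, search, g4, open_margin)
}

# Maximal unpaired segments of each strand in a state, given paired ranges.
unpaired_segments <- function(len, paired) {
  covered <- rep(FALSE, len)
  if (nrow(paired) > 0) {
    for (r in seq_len(nrow(paired))) {
      covered[paired$start[r]:paired$end[r]] <- TRUE
    }
  }
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tibble::tibble(start = starts, end = ends)[!runs$values, , drop = FALSE]
}

#' Count G-quadruplexes in a resolved state
#'
#' Applies the split-quadruplex junction rule and the intramolecular rule of
#' [g4_config()] to the unpaired regions of an [resolve_state()] output.
#' For each duplex end, guanine tracts on the two flanking unpaired
#' overhangs within `junction_window` nt of the junction are pooled; the
#' junction contributes one quadruplex when the pool reaches
#' `tracts_required`. Remaining (unconsumed) tracts contribute one
#' quadruplex per unpaired region that holds `tracts_required` tracts
#' within `intramol_span` nt. Tracts at paired positions never count.
#'
#' @param state An `mb_state`.
#' @param g4 A [g4_config()].
#' @param detail Also return per-junction/per-region detail.
#' @return Integer count, or a list with `count` and `detail` when
#'   `detail = TRUE`.
#' @export
count_g_quadruplexes <- function(state, g4 = g4_config(), detail = FALSE) {
  strands <- state$strands
  seqs <- stats::setNames(strands$sequence, strands$name)
  lens <- stats::setNames(nchar(strands$sequence), strands$name)
  paired <- stats::setNames(
    rep(list(tibble::tibble(start = integer(), end = integer())), nrow(strands)),
    strands$name
  )
  add_range <- function(nm, s, e) {
    paired[[nm]] <<- dplyr::bind_rows(
      paired[[nm]],
      tibble::tibble(start = as.integer(s), end = as.integer(e))
    )
  }
  dup <- state$duplexes
  if (nrow(dup) > 0) {
    for (r in seq_len(nrow(dup))) {
      add_range(dup$strand_a[r], dup$a_start[r], dup$a_end[r])
      add_range(dup$strand_b[r], dup$b_start[r], dup$b_end[r])
    }
  }
  if (!is.null(state$hairpin) && !is.na(state$beacon)) {
    s <- state$hairpin$stem_len
    L <- lens[[state$beacon]]
    add_range(state$beacon, 1L, s)
    add_range(state$beacon, L - s + 1L, L)
  }
  tracts <- lapply(strands$name, function(nm) {
    tr <- find_g_tracts(seqs[[nm]], g4$min_tract_len)
    tr$strand <- nm
    tr$consumed <- rep(FALSE, nrow(tr))
    tr
  })
  tracts <- dplyr::bind_rows(tracts)
  in_unpaired <- function(nm, s, e) {
    segs <- unpaired_segments(lens[[nm]], paired[[nm]])
    any(segs$start <= s & segs$end >= e)
  }
  count <- 0L
  detail_rows <- list()
  # --- junction rule ---
  if (nrow(dup) > 0) {
    for (r in seq_len(nrow(dup))) {
      a <- dup$strand_a[r]
      b <- dup$strand_b[r]
      # junction 1: a's 5' side meets b's 3' side; junction 2: the reverse
      junctions <- list(
        list(
          list(strand = a, side = "prefix", at = dup$a_start[r]),
          list(strand = b, side = "suffix", at = dup$b_end[r])
        ),
        list(
          list(strand = a, side = "suffix", at = dup$a_end[r]),
          list(strand = b, side = "prefix", at = dup$b_start[r])
        )
      )
      for (jn in seq_along(junctions)) {
        hit_idx <- integer(0)
        for (ov in junctions[[jn]]) {
          cand <- which(tracts$strand == ov$strand & !tracts$consumed)
          for (t in cand) {
            s <- tracts$start[t]
            e <- tracts$end[t]
            dist <- if (ov$side == "prefix") ov$at - e else s - ov$at
            if (dist < 1 || dist > g4$junction_window) next
            if (!in_unpaired(ov$strand, s, e)) next
            hit_idx <- c(hit_idx, t)
          }
        }
        if (length(hit_idx) >= g4$tracts_required) {
          count <- count + 1L
          tracts$consumed[hit_idx] <- TRUE
          detail_rows[[length(detail_rows) + 1L]] <- tibble::tibble(
            kind = "junction", strand_a = a, strand_b = b,
            junction = jn, tracts = length(hit_idx)
          )
        }
      }
    }
  }
  # --- intramolecular rule ---
  for (nm in strands$name) {
    segs <- unpaired_segments(lens[[nm]], paired[[nm]])
    if (nrow(segs) == 0) next
    for (r in seq_len(nrow(segs))) {
      idx <- which(
        tracts$strand == nm & !tracts$consumed &
          tracts$start >= segs$start[r] & tracts$end <= segs$end[r]
      )
      if (length(idx) < g4$tracts_required) next
      starts <- tracts$start[idx]
      ends <- tracts$end[idx]
      k <- g4$tracts_required
      spans <- ends[seq(k, length(idx))] - starts[seq_len(length(idx) - k + 1L)] + 1L
      if (any(spans <= g4$intramol_span)) {
        count <- count + 1L
        first <- which(spans <= g4$intramol_span)[1]
        tracts$consumed[idx[seq(first, first + k - 1L)]] <- TRUE
        detail_rows[[length(detail_rows) + 1L]] <- tibble::tibble(
          kind = "intramolecular", strand_a = nm, strand_b = nm,
          junction = NA_integer_, tracts = k
        )
      }
    }
  }
  if (!detail) {
    return(count)
  }
  detail_tbl <- if (length(detail_rows)) {
    dplyr::bind_rows(detail_rows)
  } else {
    tibble::tibble(
      kind = character(), strand_a = character(), strand_b = character(),
      junction = integer(), tracts = integer()
    )
  }
  list(count = count, detail = detail_tbl)
}

#' @export
print.mb_state <- function(x, ...) {
  cat("<mb_state>", nrow(x$strands), "strand(s), total dG =",
    sprintf("%.2f", x$total_dG), "kcal/mol\n")
  if (nrow(x$duplexes) > 0) {
    for (r in seq_len(nrow(x$duplexes))) {
      cat(sprintf(
        "  duplex %s[%d..%d] : %s[%d..%d]  dG = %.2f (%d mm)\n",
        x$duplexes$strand_a[r], x$duplexes$a_start[r], x$duplexes$a_end[r],
        x$duplexes$strand_b[r], x$duplexes$b_start[r], x$duplexes$b_end[r],
        x$duplexes$dG[r], x$duplexes$mismatches[r]
      ))
    }
  }
  if (!is.null(x$hairpin)) {
    cat(sprintf(
      "  beacon %s closed (stem %d bp, dG = %.2f)\n",
      x$beacon, x$hairpin$stem_len, x$hairpin$dG
    ))
  }
  if (length(x$free)) cat("  free:", paste(x$free, collapse = ", "), "\n")
  cat(
    "  beacon open:", x$beacon_open,
    " G-quadruplexes:", x$g4_count, "\n"
  )
  invisible(x)
}
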