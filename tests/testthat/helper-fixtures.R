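# shared thermodynamic parameters and a design cache so each circuit is
# designed only once per test run
tp <- mblogic::thermo_params()

.design_cache <- new.env(parent = emptyenv())

cached_design <- function(kind, seed = 1) {
  key <- paste(kind, seed, sep = "#")
  if (is.null(.design_cache[[key]])) {
    .design_cache[[key]] <- design_strands(kind, seed, params = tp)
  }
  .design_cache[[key]]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate one position of a DNA string to a different base
mutate_base <- function(seq, pos) {
  cur <- substr(seq, pos, pos)
  repl <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  paste0(substr(seq, 1, pos - 1), repl, substr(seq, pos + 1, nchar(seq)))
}

# independent brute-force enumeration of antiparallel gapless windows:
# loops over every (a_start, b_end, length) triple and counts mismatches
# directly, with no shared code with the package implementation
brute_windows <- function(a, b, min_len, max_mm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rows <- list()
  for (a_start in seq_along(ac)) {
    for (b_end in seq_along(bc)) {
      max_len <- min(length(ac) - a_start + 1L, b_end)
      if (max_len < min_len) next
      for (len in seq(min_len, max_len)) {
        ai <- a_start + 0:(len - 1L)
        bi <- b_end - 0:(len - 1L)
        mm <- sum(comp[ac[ai]] != bc[bi])
        if (mm <= max_mm) {
          rows[[length(rows) + 1L]] <- data.frame(
            a_start = a_start, a_end = a_start + len - 1L,
            b_start = b_end - len + 1L, b_end = b_end,
            length = len, mismatches = mm
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      a_start = integer(), a_end = integer(), b_start = integer(),
      b_end = integer(), length = integer(), mismatches = integer()
    ))
  }
  do.call(rbind, rows)
}

sort_windows <- function(df) {
  df <- as.data.frame(df)[c(
    "a_start", "a_end", "b_start", "b_end", "length", "mismatches"
  )]
  df <- df[order(df$a_start, df$a_end, df$b_start, df$b_end), ]
  rownames(df) <- NULL
  df
}

# independent free-energy oracle: reads the shipped parameter file on its
# own and walks the pairing position by position
oracle_duplex_dg <- function(a, b, win) {
  path <- system.file("extdata", "nn_dg37.tsv", package = "mblogic")
  raw <- read.table(path, sep = "\t", comment.char = "#",
    col.names = c("key", "value"), stringsAsFactors = FALSE)
  val <- setNames(raw$value, raw$key)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  ai <- win$a_start:win$a_end
  bi <- win$b_end:win$b_start
  wc <- comp[ac[ai]] == bc[bi]
  L <- length(ai)
  total <- val[["initiation"]]
  for (t in seq_len(L - 1L)) {
    if (wc[t] && wc[t + 1L]) {
      total <- total + val[[paste0(ac[ai[t]], ac[ai[t + 1L]])]]
    }
  }
  for (t in seq_len(L)) {
    if (!wc[t]) {
      total <- total + if (t == 1L || t == L) {
        val[["mismatch_terminal"]]
      } else {
        val[["mismatch_internal"]]
      }
    }
  }
  unname(total)
}

# random small strand sets exercising the matching solver: a few unrelated
# strands plus some near-complementary pairs so non-trivial matchings exist
random_strand_set <- function(n_strands, with_beacon = TRUE) {
  seqs <- character(0)
  while (length(seqs) < n_strands) {
    if (length(seqs) >= 1 && runif(1) < 0.6) {
      partner <- reverse_complement(sample(seqs, 1))
      if (runif(1) < 0.5) partner <- mutate_base(partner, sample(nchar(partner), 1))
      seqs <- c(seqs, partner)
    } else {
      seqs <- c(seqs, random_dna(sample(10:16, 1)))
    }
  }
  roles <- rep("input", n_strands)
  if (with_beacon) roles[1] <- "beacon"
  strand_set(
    name = sprintf("S%d", seq_len(n_strands)),
    sequence = seqs, role = roles,
    require_beacon = FALSE
  )
}

expect_same_state <- function(resolved, brute) {
  expect_equal(resolved$total_dG, brute$total_dG, tolerance = 1e-9)
  key <- function(st) {
    if (nrow(st$duplexes) == 0) {
      return("")
    }
    paste(sort(paste(
      pmin(st$duplexes$strand_a, st$duplexes$strand_b),
      pmax(st$duplexes$strand_a, st$duplexes$strand_b)
    )), collapse = ";")
  }
  expect_identical(key(resolved), key(brute))
  expect_identical(resolved$g4_count, brute$g4_count)
  expect_identical(resolved$beacon_open, brute$beacon_open)
}
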