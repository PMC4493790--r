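#' Read paired 5'/3' LTR sequences from FASTA
#'
#' Expects two records per element, with ids suffixed `_5LTR` and `_3LTR`
#' (case-insensitive). Elements missing one of the two records are dropped
#' with a warning.
#'
#' @param file Path to a FASTA file.
#' @returns A tibble with columns `element`, `ltr5`, `ltr3` (uppercase
#'   strings).
#' @export
read_ltr_pairs <- function(file) {
  seqs <- ape::read.FASTA(file)
  txt <- vapply(as.character(seqs),
                function(x) toupper(paste(x, collapse = "")), "")
  ids <- names(txt)
  suf <- sub(".*_([35])LTR$", "\\1", ids, ignore.case = TRUE)
  el <- sub("_[35]LTR$", "", ids, ignore.case = TRUE)
  if (any(!suf %in% c("3", "5"))) {
    abort("FASTA record ids must end in _5LTR or _3LTR",
          class = "tedose_malformed_input")
  }
  wide <- tibble(element = el, end = suf, seq = unname(txt)) |>
    tidyr::pivot_wider(names_from = "end", values_from = "seq",
                       names_prefix = "ltr")
  incomplete <- is.na(wide$ltr5) | is.na(wide$ltr3)
  if (any(incomplete)) {
    warn(paste0("dropping element(s) without both LTRs: ",
                paste(wide$element[incomplete], collapse = ", ")))
    wide <- wide[!incomplete, ]
  }
  wide[c("element", "ltr5", "ltr3")]
}

nw_score <- function(a, b, match, mismatch) {
  if (a == b && a %in% c("A", "C", "G", "T")) match else mismatch
}

#' Global pairwise alignment of two LTR sequences
#'
#' Needleman-Wunsch global alignment with affine gap costs (Gotoh
#' recursion). A gap of length `L` scores `gap_open + (L - 1) *
#' gap_extend`, i.e. the opening position carries the open penalty.
#' Traceback ties are resolved deterministically, preferring substitution
#' over a gap in the second sequence over a gap in the first.
#'
#' @param ltr5,ltr3 Unaligned nucleotide strings (`A/C/G/T/N`).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults
#'   +1/-1/-5/-1). `N` scores as a mismatch against everything.
#' @returns A list with `ltr5`, `ltr3` (gapped aligned strings), `score`,
#'   and `identity` (fraction of identical columns among gap-free
#'   columns).
#' @export
#' @examples
#' align_ltrs("ACGTACGT", "ACGACGT")
align_ltrs <- function(ltr5, ltr3, match = 1, mismatch = -1,
                       gap_open = -5, gap_extend = -1) {
  a <- strsplit(toupper(ltr5), "")[[1]]
  b <- strsplit(toupper(ltr3), "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) {
    abort("empty sequence", class = "tedose_malformed_input")
  }
  NEG <- -1e18
  gap_len <- function(L) gap_open + (L - 1) * gap_extend
  M <- matrix(NEG, n + 1, m + 1)
  IX <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  IY <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) IX[i + 1, 1] <- gap_len(i)
  for (j in seq_len(m)) IY[1, j + 1] <- gap_len(j)

  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- nw_score(a[i], b[j], match, mismatch)
      M[i + 1, j + 1] <- s + max(M[i, j], IX[i, j], IY[i, j])
      IX[i + 1, j + 1] <- max(M[i, j + 1] + gap_open,
                              IX[i, j + 1] + gap_extend)
      IY[i + 1, j + 1] <- max(M[i + 1, j] + gap_open,
                              IY[i + 1, j] + gap_extend)
    }
  }
  score <- max(M[n + 1, m + 1], IX[n + 1, m + 1], IY[n + 1, m + 1])

  # traceback; tie preference M > IX > IY
  state <- c("M", "IX", "IY")[which.max(c(M[n + 1, m + 1], IX[n + 1, m + 1],
                                          IY[n + 1, m + 1]))]
  i <- n; j <- m
  out_a <- character(0); out_b <- character(0)
  while (i > 0 || j > 0) {
    if (state == "M" && i > 0 && j > 0) {
      s <- nw_score(a[i], b[j], match, mismatch)
      prev <- c(M[i, j], IX[i, j], IY[i, j])
      state_new <- c("M", "IX", "IY")[which.max(prev)]
      out_a <- c(a[i], out_a); out_b <- c(b[j], out_b)
      i <- i - 1; j <- j - 1
      state <- state_new
    } else if (state == "IX" || (j == 0 && i > 0)) {
      out_a <- c(a[i], out_a); out_b <- c("-", out_b)
      from_m <- M[i, j + 1] + gap_open
      from_ix <- IX[i, j + 1] + gap_extend
      state <- if (from_m >= from_ix) "M" else "IX"
      i <- i - 1
    } else {
      out_a <- c("-", out_a); out_b <- c(b[j], out_b)
      from_m <- M[i + 1, j] + gap_open
      from_iy <- IY[i + 1, j] + gap_extend
      state <- if (from_m >= from_iy) "M" else "IY"
      j <- j - 1
    }
  }
  gap_free <- out_a != "-" & out_b != "-"
  list(
    ltr5 = paste(out_a, collapse = ""),
    ltr3 = paste(out_b, collapse = ""),
    score = score,
    identity = if (any(gap_free)) mean(out_a[gap_free] == out_b[gap_free])
               else NA_real_
  )
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura two-parameter divergence between two aligned sequences
#'
#' Transitions (`P`) and transversions (`Q`) are counted over columns where
#' both sequences carry an unambiguous base (gap or `N` columns are
#' excluded pairwise, the two-sequence analogue of complete deletion), and
#' `k = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`. Saturated alignments
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) raise an error rather than being
#' clamped.
#'
#' @param ltr5,ltr3 Aligned sequences of equal length over
#'   `A/C/G/T/N/-`.
#' @returns A one-row tibble with `k`, `P`, `Q`, `sites_used`.
#' @export
#' @examples
#' k2p_distance(strrep("ACGT", 60), strrep("ACGT", 60))  # identical -> k = 0
k2p_distance <- function(ltr5, ltr3) {
  x <- strsplit(toupper(ltr5), "")[[1]]
  y <- strsplit(toupper(ltr3), "")[[1]]
  if (length(x) != length(y)) {
    abort("sequences must be aligned to equal length (see align_ltrs)",
          class = "tedose_malformed_input")
  }
  ok <- x %in% c(PURINES, PYRIMIDINES) & y %in% c(PURINES, PYRIMIDINES)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0) {
    abort("no usable (unambiguous, gap-free) sites",
          class = "tedose_malformed_input")
  }
  diff <- x != y
  same_class <- (x %in% PURINES) == (y %in% PURINES)
  P <- sum(diff & same_class) / n   # transitions
  Q <- sum(diff & !same_class) / n  # transversions
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    abort("sequences are saturated; K2P distance undefined",
          class = "tedose_saturation")
  }
  k <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  k <- k + 0  # normalise IEEE signed zero for identical sequences
  tibble(k = k, P = P, Q = Q, sites_used = n)
}

#' Molecular-clock insertion date from LTR divergence
#'
#' The two LTRs of an element are identical at insertion and each
#' accumulates substitutions at rate `r` afterwards, so their divergence
#' `k` grows at `2r` per year and the insertion age is `T = k / (2r)`.
#'
#' @param k K2P divergence between the 5' and 3' LTR (substitutions/site).
#' @param rate Substitution rate `r` in substitutions per site per year
#'   (default 1.3e-8, a rate commonly applied to grass LTR
#'   retrotransposons).
#' @returns Insertion age in years (vectorized over `k`).
#' @export
#' @examples
#' insertion_date(0)                     # identical LTRs: age 0
#' insertion_date(0.0078) / 1e6          # ~0.30 mya
insertion_date <- function(k, rate = 1.3e-8) {
  if (rate <= 0) abort("rate must be positive", class = "tedose_configuration")
  if (any(k < 0)) abort("k must be non-negative", class = "tedose_invalid_input")
  k / (2 * rate)
}

#' Date LTR-retrotransposon insertions for a table of LTR pairs
#'
#' For each element, aligns the 5' and 3' LTR when needed (`align =
#' "auto"` aligns unless the sequences already have equal length or contain
#' gap characters), computes the K2P divergence and applies the molecular
#' clock.
#'
#' @param pairs Tibble with columns `element`, `ltr5`, `ltr3` (see
#'   [read_ltr_pairs()] or [simulate_ltr_pairs()]).
#' @param rate Substitution rate per site per year.
#' @param align `"auto"`, `TRUE` (always align) or `FALSE` (never).
#' @returns A tibble with `element`, `k`, `P`, `Q`, `sites`, `T_years`,
#'   `T_mya`.
#' @export
#' @examples
#' pairs <- simulate_ltr_pairs(ltr_scenario(age_years = 0, seed = 1))
#' date_insertions(pairs)
date_insertions <- function(pairs, rate = 1.3e-8, align = "auto") {
  stopifnot(all(c("element", "ltr5", "ltr3") %in% names(pairs)))
  purrr::pmap_dfr(
    pairs[c("element", "ltr5", "ltr3")],
    function(element, ltr5, ltr3) {
      do_align <- isTRUE(align) ||
        (identical(align, "auto") && nchar(ltr5) != nchar(ltr3) &&
           !grepl("-", paste0(ltr5, ltr3)))
      if (do_align) {
        al <- align_ltrs(ltr5, ltr3)
        ltr5 <- al$ltr5; ltr3 <- al$ltr3
      }
      div <- k2p_distance(ltr5, ltr3)
      tibble(
        element = element, k = div$k, P = div$P, Q = div$Q,
        sites = div$sites_used,
        T_years = insertion_date(div$k, rate),
        T_mya = insertion_date(div$k, rate) / 1e6
      )
    }
  )
}
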