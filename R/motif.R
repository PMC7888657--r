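# Promoter operator scanning: anaerobox (TTGAT-N4-ATCAA, a palindrome) and
# K-box (GTTACA-N4-GTTACA, a direct repeat), reported at TSS-relative
# offsets with the no-zero convention used for bacterial operator maps.

motif_consensus <- function(kind) {
  switch(kind,
         anaerobox = "TTGATNNNNATCAA",
         kbox = "GTTACANNNNGTTACA",
         stop("unknown motif kind: ", kind, call. = FALSE))
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  paste(rev(DNA_COMP[strsplit(x, "")[[1]]]), collapse = "")
}

# 1-based sequence position -> TSS-relative offset (TSS = +1, no zero).
pos_to_offset <- function(pos, tss) ifelse(pos >= tss, pos - tss + 1, pos - tss)

# TSS-relative offset -> 1-based sequence position.
offset_to_pos <- function(offset, tss) {
  if (any(offset == 0)) stop("offset 0 does not exist (TSS = +1)",
                             call. = FALSE)
  ifelse(offset > 0, tss + offset - 1, tss + offset)
}

# Mismatch counts of a consensus (with N wildcards) against every window of
# a subject sequence; returns an integer vector over start positions.
window_mismatches <- function(subject_chars, consensus) {
  pat <- strsplit(consensus, "")[[1]]
  w <- length(pat)
  n_win <- length(subject_chars) - w + 1
  if (n_win < 1) return(integer(0))
  mm <- integer(n_win)
  for (j in seq_len(w)) {
    if (pat[j] == "N") next
    mm <- mm + (subject_chars[j:(j + n_win - 1)] != pat[j])
  }
  mm
}

#' Scan a promoter sequence for anaerobox and K-box operators
#'
#' Exhaustive sliding-window match of the anaerobox consensus
#' (`TTGAT-N4-ATCAA`) and K-box consensus (`GTTACA-N4-GTTACA`) on both
#' strands of a promoter region around a transcription start site. Offsets
#' follow the bacterial operator-map convention: position of the motif's
#' 5'-most base on the forward strand relative to the TSS, with the TSS
#' base at +1, negative offsets upstream and no position 0. The anaerobox
#' is an exact palindrome, so coinciding forward and reverse matches are
#' reported once on the forward strand; the K-box is a direct repeat and is
#' scanned on both strands independently.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param tss 1-based position of the transcription start site within
#'   `sequence`.
#' @param window Integer pair `(upstream, downstream)`: scanned offsets
#'   relative to the TSS; default `c(-200, 60)`.
#' @param max_mismatches Allowed mismatches per hit (default 0: the
#'   consensus is treated as exact).
#' @return A tibble with columns `motif` (`"anaerobox"`/`"kbox"`), `strand`
#'   (`"forward"`/`"reverse"`), `offset`, `match` (the forward-strand
#'   sequence of the matched window) and `mismatches`, sorted by offset.
#' @export
#' @examples
#' fx <- promoter_fixture("anaerobox", offset = -34, seed = 1)
#' scan_sequence(fx$sequence, fx$tss)
scan_sequence <- function(sequence, tss, window = c(-200, 60),
                          max_mismatches = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains characters outside {A, C, G, T, N}",
         call. = FALSE)
  }
  if (tss < 1 || tss > length(chars)) {
    stop("TSS coordinate lies outside the sequence", call. = FALSE)
  }
  stopifnot(length(window) == 2, window[1] < window[2])
  hits <- list()
  for (kind in c("anaerobox", "kbox")) {
    cons <- motif_consensus(kind)
    w <- nchar(cons)
    fwd_mm <- window_mismatches(chars, cons)
    rev_mm <- window_mismatches(chars, revcomp(cons))
    for (start in seq_along(fwd_mm)) {
      off <- as.integer(pos_to_offset(start, tss))
      if (off < window[1] || off > window[2]) next
      matched <- substr(sequence, start, start + w - 1)
      fwd_ok <- fwd_mm[start] <= max_mismatches
      rev_ok <- rev_mm[start] <= max_mismatches
      if (fwd_ok) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          motif = kind, strand = "forward", offset = off, match = matched,
          mismatches = fwd_mm[start])
      }
      # palindromic anaerobox: a coinciding reverse hit duplicates the
      # forward hit and is suppressed; the K-box direct repeat is not
      if (rev_ok && !(kind == "anaerobox" && fwd_ok)) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          motif = kind, strand = "reverse", offset = off, match = matched,
          mismatches = rev_mm[start])
      }
    }
  }
  out <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(motif = character(0), strand = character(0),
                   offset = integer(0), match = character(0),
                   mismatches = integer(0))
  dplyr::arrange(out, .data$offset, .data$motif, .data$strand)
}

#' Generate a synthetic promoter with a planted operator
#'
#' Random motif-free background (by rejection against both consensi) with
#' one exact motif instance (randomised N4 spacer) planted at the requested
#' TSS-relative offset. Round-trips through [scan_sequence()].
#'
#' @param kind `"anaerobox"` or `"kbox"`.
#' @param offset TSS-relative offset of the motif's first base (non-zero).
#' @param flank Background length on each side of the TSS (default 250).
#' @param strand Strand to plant the motif on (`"forward"` or `"reverse"`;
#'   reverse plants the reverse complement).
#' @param seed Integer seed.
#' @return A list with `sequence`, `tss` (1-based coordinate) and `offset`.
#' @export
#' @examples
#' promoter_fixture("kbox", offset = -62, seed = 7)$tss
promoter_fixture <- function(kind = c("anaerobox", "kbox"), offset,
                             flank = 250, strand = c("forward", "reverse"),
                             seed = 0) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  if (offset == 0) stop("offset 0 does not exist (TSS = +1)", call. = FALSE)
  cons <- motif_consensus(kind)
  w <- nchar(cons)
  len <- 2 * flank + 1
  tss <- flank + 1
  start <- offset_to_pos(offset, tss)
  if (start < 1 || start + w - 1 > len) {
    stop("offset ", offset, " places the motif outside the ", flank,
         "-base flanks", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  repeat {
    bg <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
    clean <- nrow(scan_sequence(bg, tss, window = c(-len, len))) == 0
    if (clean) break
  }
  spacer <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                  collapse = "")
  motif <- sub("NNNN", spacer, cons, fixed = TRUE)
  if (strand == "reverse") motif <- revcomp(motif)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  seq_out <- paste0(substr(bg, 1, start - 1), motif,
                    substr(bg, start + w, len))
  list(sequence = seq_out, tss = tss, offset = offset)
}

#' Scan FASTA promoter sequences against a TSS table
#'
#' File-level interface to [scan_sequence()]: reads sequences from a FASTA
#' file (via Biostrings) and TSS coordinates from a tab-separated table with
#' columns `name`, `tss` (1-based position within the corresponding FASTA
#' record) and optional `strand`.
#'
#' @param fasta Path to a FASTA file.
#' @param tss_table Path to a tab-separated TSS table, or a data frame.
#' @param ... Passed to [scan_sequence()].
#' @return A tibble of hits with a `name` column prepended.
#' @export
scan_fasta <- function(fasta, tss_table, ...) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("scan_fasta() requires the Biostrings package", call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  tt <- if (is.data.frame(tss_table)) tss_table else
    utils::read.delim(tss_table, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "tss") %in% names(tt)))
  purrr::pmap_dfr(tt[c("name", "tss")], function(name, tss) {
    if (!name %in% names(seqs)) {
      stop("TSS table names sequence '", name, "' absent from the FASTA",
           call. = FALSE)
    }
    hits <- scan_sequence(as.character(seqs[[name]]), tss, ...)
    dplyr::mutate(hits, name = name, .before = 1)
  })
}
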