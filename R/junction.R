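#' Random DNA sequence generation
#'
#' @param n Sequence length.
#' @param seed Optional integer seed.
#' @return A character scalar over \{A, C, G, T\}.
#' @export
random_dna <- function(n, seed = NULL) {
  with_seed(seed,
            paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""))
}

#' Reverse complement of a DNA string
#'
#' @param x DNA character scalar.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

.check_dna <- function(x, what) {
  if (!grepl("^[ACGT]*$", x))
    stop_dfm(what, " must be a DNA string over {A,C,G,T}")
}

#' Construct a synthetic Tn7 junction read
#'
#' Models the sequenced region from the 3' end of glmS to the right end of
#' the transposon (Tn7-R): the read is the glmS reference (ending at its
#' stop codon), followed by `offset` bases of the downstream genomic
#' region, followed by the Tn7-R sequence.  The `dup_len` bases
#' immediately preceding the insertion point are the target-site
#' duplication and are recorded as ground truth together with the offset.
#'
#' @param glms_ref DNA string ending with a stop codon (TAA/TAG/TGA).
#' @param downstream DNA string downstream of the stop codon, length >=
#'   `offset`.
#' @param offset Insertion distance in bp from the stop codon (>=
#'   `dup_len`).
#' @param dup_len Target-site duplication length (default 5).
#' @param tn7r_seq Tn7-R anchor DNA string.
#' @return A list of class `junction_record`: `read_seq`, `glms_ref`,
#'   `tn7r_seq`, `truth_offset`, `truth_dup`.
#' @export
#' @examples
#' gl <- paste0(random_dna(60, seed = 1), "TAA")
#' jr <- make_junction(gl, random_dna(50, seed = 2), offset = 25,
#'                     tn7r_seq = random_dna(30, seed = 3))
#' jr$truth_offset
make_junction <- function(glms_ref, downstream, offset, dup_len = 5,
                          tn7r_seq) {
  .check_dna(glms_ref, "glms_ref"); .check_dna(downstream, "downstream")
  .check_dna(tn7r_seq, "tn7r_seq")
  if (!substring(glms_ref, nchar(glms_ref) - 2) %in% c("TAA", "TAG", "TGA"))
    stop_dfm("glms_ref must end with a stop codon (TAA/TAG/TGA)")
  if (offset < dup_len) stop_dfm("offset must be >= dup_len")
  if (offset > nchar(downstream))
    stop_dfm("offset exceeds downstream length")
  ins <- substring(downstream, 1, offset)
  dup <- if (dup_len > 0) substring(ins, offset - dup_len + 1, offset) else ""
  structure(
    list(read_seq = paste0(glms_ref, ins, tn7r_seq),
         glms_ref = glms_ref, tn7r_seq = tn7r_seq,
         truth_offset = offset, truth_dup = dup),
    class = "junction_record")
}

# Positions (1-based) where `pattern` occurs in `subject` with at most
# `max_mm` mismatches; exact matching uses fixed gregexpr with overlap.
.find_anchor <- function(subject, pattern, max_mm = 0) {
  np <- nchar(pattern); ns <- nchar(subject)
  if (np > ns) return(integer())
  if (max_mm == 0) {
    hits <- integer(); from <- 1
    repeat {
      p <- regexpr(pattern, substring(subject, from), fixed = TRUE)
      if (p == -1) break
      hits <- c(hits, from + p - 1)
      from <- from + p
    }
    return(hits)
  }
  subj <- strsplit(subject, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  starts <- seq_len(ns - np + 1)
  starts[vapply(starts, function(i)
    sum(subj[i:(i + np - 1)] != pat) <= max_mm, logical(1))]
}

#' Call the Tn7 attB insertion offset and target-site duplication
#'
#' Anchors the read with the 3'-terminal `anchor_len` bases of the glmS
#' reference and the first `tn7_anchor_len` bases of Tn7-R (exact
#' substring matches, each required exactly once and non-overlapping;
#' optionally up to `max_mm` mismatches via a Hamming scan).  The offset
#' is the number of bases strictly between the stop codon's last base and
#' the start of the Tn7-R match; the duplication is the `dup_len` bases
#' immediately preceding the insertion point.  If the forward orientation
#' fails, the reverse complement of the read is tried automatically.
#'
#' @param rec A `junction_record` (or list with `read_seq`, `glms_ref`,
#'   `tn7r_seq`).
#' @param dup_len Duplication length to report (default 5).
#' @param anchor_len glmS anchor length (>= 30, default 30).
#' @param tn7_anchor_len Tn7-R anchor length (>= 20, default 20).
#' @param max_mm Maximum mismatches per anchor (default 0, exact).
#' @return A list of class `att_call`: `offset_bp`, `dup_seq`, `dup_len`,
#'   `valid`, `notes`.
#' @export
#' @examples
#' gl <- paste0(random_dna(60, seed = 1), "TAA")
#' jr <- make_junction(gl, random_dna(50, seed = 2), offset = 25,
#'                     tn7r_seq = random_dna(30, seed = 3))
#' call_att(jr)$offset_bp
call_att <- function(rec, dup_len = 5, anchor_len = 30,
                     tn7_anchor_len = 20, max_mm = 0) {
  if (anchor_len < 30) stop_dfm("glmS anchor must be >= 30 bp")
  if (tn7_anchor_len < 20) stop_dfm("Tn7-R anchor must be >= 20 bp")
  ga <- substring(rec$glms_ref, nchar(rec$glms_ref) - anchor_len + 1)
  ta <- substring(rec$tn7r_seq, 1, tn7_anchor_len)
  fail <- function(msg) structure(
    list(offset_bp = NA_integer_, dup_seq = NA_character_,
         dup_len = NA_integer_, valid = FALSE, notes = msg),
    class = "att_call")
  attempt <- function(read) {
    g_hits <- .find_anchor(read, ga, max_mm)
    if (length(g_hits) != 1)
      return(fail(sprintf("glmS anchor found %d times", length(g_hits))))
    g_end <- g_hits + nchar(ga) - 1
    t_hits <- .find_anchor(read, ta, max_mm)
    t_hits <- t_hits[t_hits > g_hits]
    if (length(t_hits) != 1)
      return(fail(sprintf(
        "Tn7-R anchor found %d times downstream of glmS", length(t_hits))))
    if (t_hits <= g_end) return(fail("anchors overlap"))
    offset <- t_hits - g_end - 1L
    dl <- min(dup_len, offset)
    dup <- if (dl > 0) substring(read, t_hits - dl, t_hits - 1) else ""
    structure(list(offset_bp = as.integer(offset), dup_seq = dup,
                   dup_len = nchar(dup), valid = TRUE, notes = ""),
              class = "att_call")
  }
  res <- attempt(rec$read_seq)
  if (!res$valid) {
    rc <- attempt(revcomp(rec$read_seq))
    if (rc$valid) {
      rc$notes <- "called on reverse-complemented read"
      return(rc)
    }
  }
  res
}

#' Summarise attB offsets across strains
#'
#' Tabulates called offsets, checks whether all fall within +/- 1 bp of
#' the canonical insertion distance (25 bp downstream of the glmS stop
#' codon), and tallies whether the duplicated 5-mers share a consensus.
#' Positions where no base reaches the consensus fraction are reported as
#' unconserved; when none do, the note records that the duplicated
#' sequence shows no conservation (the transposon targets a distance, not
#' a sequence).
#'
#' @param calls List of `att_call` objects.
#' @param canonical Canonical offset (default 25 bp).
#' @param consensus_frac Fraction of sequences that must agree for a
#'   position to count as conserved (default 0.9).
#' @return List with `histogram` (named integer vector), `within_pm1`
#'   (logical), `consensus` (character, "" when unconserved), `note`,
#'   `n_valid`.
#' @export
summarise_offsets <- function(calls, canonical = 25, consensus_frac = 0.9) {
  valid <- Filter(function(x) isTRUE(x$valid), calls)
  if (length(valid) == 0) stop_dfm("no valid attB calls")
  offs <- vapply(valid, function(x) x$offset_bp, integer(1))
  hist <- table(offs)
  within <- all(abs(offs - canonical) <= 1)
  dups <- vapply(valid, function(x) x$dup_seq, character(1))
  dups <- dups[nchar(dups) > 0]
  consensus <- ""
  if (length(dups) > 1 && length(unique(nchar(dups))) == 1) {
    m <- do.call(rbind, strsplit(dups, ""))
    cons <- apply(m, 2, function(col) {
      tb <- table(col)
      if (max(tb) / length(col) >= consensus_frac) names(which.max(tb))
      else "N"
    })
    consensus <- paste(cons, collapse = "")
  }
  conserved <- nzchar(consensus) && !grepl("N", consensus)
  list(
    histogram = stats::setNames(as.integer(hist), names(hist)),
    within_pm1 = within,
    consensus = if (conserved) consensus else "",
    note = if (conserved)
      "duplicated target sites share a consensus sequence"
    else "no conservation in the duplicated target-site sequence",
    n_valid = length(valid))
}

#' Write / read junction records as FASTA
#'
#' Plain-text FASTA with one record per read; headers carry the record
#' names.  Uses Biostrings when available, otherwise a minimal built-in
#' writer/reader.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path FASTA path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (nm in names(seqs))
      writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.character(ss), names(ss)))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  stopifnot(length(idx) > 0)
  ends <- c(idx[-1] - 1, length(lines))
  seqs <- vapply(seq_along(idx), function(i)
    paste(lines[(idx[i] + 1):ends[i]], collapse = ""), character(1))
  stats::setNames(seqs, sub("^>\\s*", "", sub("\\s.*$", "", lines[idx])))
}
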