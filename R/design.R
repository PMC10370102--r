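#' Peptide dye-label design
#'
#' Describes which residue positions of a peptide carry fluorophores of which
#' color channel, and how many Edman cycles the experiment performs. Reads
#' have `n_cycles + 1` imaging timepoints because the peptide is imaged once
#' before any Edman chemistry.
#'
#' @param labels Positions carrying dyes: either an integer vector (single
#'   channel) or a list of integer vectors, one per channel. Positions are
#'   1-based residue indices.
#' @param n_cycles Number of Edman degradation cycles (>= 1).
#' @param nterm Optional N-terminus annotation (e.g. `"ac"`, `"fmoc"`,
#'   `"NH2"`); metadata only, it does not change the model.
#'
#' @return An object of class `peptide_design`.
#' @examples
#' # one color, labels at positions 2 and 4, ten Edman cycles
#' peptide_design(c(2, 4), n_cycles = 10)
#' @export
peptide_design <- function(labels, n_cycles, nterm = NA_character_) {
  if (!is.list(labels)) labels <- list(labels)
  labels <- lapply(labels, function(x) sort(as.integer(x)))
  if (sum(lengths(labels)) < 1L) {
    stop("design must carry at least one labeled position", call. = FALSE)
  }
  for (pos in labels) {
    if (anyDuplicated(pos) || any(pos < 1L)) {
      stop("label positions within a channel must be distinct and >= 1",
        call. = FALSE
      )
    }
  }
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  structure(
    list(
      labels_by_channel = labels,
      n_channels = length(labels),
      n_cycles = n_cycles,
      nterm = nterm
    ),
    class = "peptide_design"
  )
}

#' @export
print.peptide_design <- function(x, ...) {
  cat("<peptide_design> ", x$n_channels, " channel(s), ",
    x$n_cycles, " Edman cycles\n",
    sep = ""
  )
  for (ch in seq_len(x$n_channels)) {
    cat(
      "  ch", ch - 1L, ": positions ",
      paste(x$labels_by_channel[[ch]], collapse = ", "), "\n",
      sep = ""
    )
  }
  if (!is.na(x$nterm)) cat("  N-terminus: ", x$nterm, "\n", sep = "")
  invisible(x)
}

# Number of channel-`ch` labels still attached after n successful Edman
# removals (positions strictly greater than n).
labels_remaining <- function(design, ch, n) {
  pos <- design$labels_by_channel[[ch]]
  vapply(n, function(ni) sum(pos > ni), integer(1))
}

# Channel (1-based) whose label sits at residue `pos`, or 0L if unlabeled.
channel_at_position <- function(design, pos) {
  for (ch in seq_len(design$n_channels)) {
    if (pos %in% design$labels_by_channel[[ch]]) {
      return(ch)
    }
  }
  0L
}

#' Parse peptide label notation
#'
#' Parses the compact peptide notation used in fluorosequencing work:
#' single-letter amino-acid codes, multi-character residues in braces (e.g.
#' `{azK}`), a `*` marking the preceding residue as dye-labeled, an optional
#' N-terminus prefix (`NH2-`, `ac-`, `fmoc-`), and an optional trailing `|`
#' indicating the sequence was truncated at the last labeled residue.
#'
#' @param s Peptide string, e.g. `"NH2-G{azK}*AG{azK}*|"`.
#' @param label_rules Named list or vector mapping residue tokens (e.g.
#'   `"K"`, `"azK"`) to 0-based channel indices. Tokens not listed may still
#'   be starred if `label_rules` is `NULL`, in which case every starred
#'   residue maps to channel 0.
#' @param n_cycles Number of Edman cycles for the resulting design.
#'
#' @return A [peptide_design()] whose `nterm` records the N-terminus tag.
#' @examples
#' parse_peptide_notation("NH2-G{azK}*AG{azK}*|", list(azK = 0), n_cycles = 10)
#' parse_peptide_notation("fmoc-APK*|", list(K = 0), n_cycles = 10)
#' @export
parse_peptide_notation <- function(s, label_rules = NULL, n_cycles = 10) {
  stopifnot(is.character(s), length(s) == 1L)
  s0 <- trimws(s)
  nterm <- NA_character_
  m <- regmatches(s0, regexec("^(NH_?2_?|ac|fmoc)-", s0))[[1]]
  if (length(m)) {
    nterm <- gsub("_", "", m[2])
    s0 <- substring(s0, nchar(m[1]) + 1L)
  }
  s0 <- sub("[|∣]$", "", s0)

  tokens <- character(0)
  starred <- logical(0)
  i <- 1L
  while (i <= nchar(s0)) {
    chr <- substring(s0, i, i)
    if (chr == "{") {
      j <- regexpr("}", substring(s0, i))
      if (j < 0) stop("unterminated '{' in peptide notation", call. = FALSE)
      tok <- substring(s0, i + 1L, i + j - 2L)
      i <- i + j
    } else if (grepl("^[A-Za-z]$", chr)) {
      tok <- chr
      i <- i + 1L
    } else if (chr == "*") {
      if (!length(tokens)) {
        stop("'*' must follow a residue token", call. = FALSE)
      }
      starred[length(starred)] <- TRUE
      i <- i + 1L
      next
    } else {
      stop("unexpected character in peptide notation: '", chr, "'",
        call. = FALSE
      )
    }
    tokens <- c(tokens, tok)
    starred <- c(starred, FALSE)
  }
  if (!any(starred)) stop("peptide has no labeled residues", call. = FALSE)

  chan <- integer(0)
  pos <- integer(0)
  for (k in which(starred)) {
    tok <- tokens[k]
    if (is.null(label_rules)) {
      ch <- 0L
    } else {
      if (is.null(label_rules[[tok]])) {
        stop("no label rule for starred residue token '", tok, "'",
          call. = FALSE
        )
      }
      ch <- as.integer(label_rules[[tok]])
    }
    chan <- c(chan, ch)
    pos <- c(pos, k)
  }
  n_channels <- max(chan) + 1L
  labels <- lapply(seq_len(n_channels) - 1L, function(c0) pos[chan == c0])
  peptide_design(labels, n_cycles = n_cycles, nterm = nterm)
}
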