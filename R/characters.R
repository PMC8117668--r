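# IUPAC nucleotide ambiguity codes as state sets over (A, C, G, T).
IUPAC_DNA <- list(
  a = "a", c = "c", g = "g", t = "t", u = "t",
  r = c("a", "g"), y = c("c", "t"), s = c("c", "g"), w = c("a", "t"),
  k = c("g", "t"), m = c("a", "c"),
  b = c("c", "g", "t"), d = c("a", "g", "t"), h = c("a", "c", "t"),
  v = c("a", "c", "g"), n = c("a", "c", "g", "t")
)

#' Character matrix (taxa x characters)
#'
#' Container for aligned discrete characters: nucleotides (`"dna"`, with
#' IUPAC ambiguities) or multistate morphology (`"standard"`, states coded
#' `0`, `1`, `2`, ...). `"?"` and `"-"` are treated as fully missing for
#' morphology; for nucleotides `"-"` is treated as missing, not as an
#' indel state.
#'
#' @param x character matrix with taxon rownames; one column per character.
#' @param type `"dna"` or `"standard"`.
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(x, type = c("standard", "dna")) {
  type <- match.arg(type)
  stopifnot(is.matrix(x))
  if (ncol(x) == 0 || nrow(x) == 0) stop("empty matrix")
  if (is.null(rownames(x))) stop("taxon rownames are required")
  x[] <- tolower(x)
  missing_sym <- c("?", "-")
  known <- if (type == "dna") names(IUPAC_DNA) else c(0:9, letters)
  bad <- setdiff(unique(as.vector(x)), c(known, missing_sym))
  if (length(bad))
    stop("unknown state symbol(s): ", paste(bad, collapse = ", "))
  structure(list(x = x, type = type, missing = missing_sym),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix [%s]: %d taxa x %d characters, %.2f%% missing\n",
              x$type, nrow(x$x), ncol(x$x), 100 * missing_fraction(x)))
  invisible(x)
}

#' Fraction of missing cells
#' @param cm a `char_matrix`.
#' @return fraction in `[0, 1]`.
#' @export
missing_fraction <- function(cm) {
  mean(cm$x %in% cm$missing)
}

#' Observed state counts per character
#'
#' Number of distinct observed (non-missing) states in each column. For the
#' Mk model the per-character state space defaults to this count (minimum
#' 2), the usual convention for mixed-state morphological matrices.
#'
#' @param cm a `char_matrix`.
#' @return integer vector of length `ncol`.
#' @export
state_counts <- function(cm) {
  apply(cm$x, 2, function(col) length(unique(col[!(col %in% cm$missing)])))
}

#' Read a character matrix from file
#'
#' @param path file path.
#' @param format `"nexus"` (DATA/CHARACTERS block, datatype standard or
#'   dna), `"fasta"`, or `"phylip"` (sequential, nucleotides).
#' @param type force `"dna"` or `"standard"`; default guesses from content.
#' @return a `char_matrix`.
#' @export
parse_character_matrix <- function(path, format = c("nexus", "fasta", "phylip"),
                                   type = NULL) {
  format <- match.arg(format)
  rows <- switch(format,
    nexus = {
      lst <- ape::read.nexus.data(path)
      do.call(rbind, lapply(lst, tolower))
    },
    fasta = {
      seqs <- ape::read.FASTA(path)
      m <- as.character(as.matrix(seqs))
      m
    },
    phylip = {
      m <- as.character(ape::read.dna(path, format = "sequential"))
      m
    })
  if (is.null(dim(rows))) stop("empty or ragged matrix")
  if (is.null(type)) {
    obs <- setdiff(unique(as.vector(tolower(rows))), c("?", "-"))
    type <- if (all(obs %in% names(IUPAC_DNA))) "dna" else "standard"
  }
  char_matrix(rows, type = type)
}

#' Write a morphological matrix as a NEXUS standard-data file
#' @param cm a `char_matrix`.
#' @param path output path.
#' @export
write_nexus_matrix <- function(cm, path) {
  sym <- sort(setdiff(unique(as.vector(cm$x)), cm$missing))
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(cm$x), ncol(cm$x)),
             sprintf("  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"%s\";",
                     paste(sym, collapse = " ")),
             "  MATRIX")
  seqs <- apply(cm$x, 1, paste, collapse = "")
  lines <- c(lines, sprintf("    %s  %s", format(rownames(cm$x)), seqs),
             "  ;", "END;")
  writeLines(lines, path)
}

#' Write a nucleotide matrix as FASTA
#' @param cm a `char_matrix` of type `"dna"`.
#' @param path output path.
#' @export
write_fasta_matrix <- function(cm, path) {
  stopifnot(cm$type == "dna")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(cm$x))) {
    writeLines(c(paste0(">", rownames(cm$x)[i]),
                 paste(cm$x[i, ], collapse = "")), con)
  }
}

# Collapse identical columns into site patterns with weights.
compress_patterns <- function(mat) {
  key <- apply(mat, 2, paste, collapse = "\r")
  tab <- table(factor(key, levels = unique(key)))
  keep <- match(names(tab), key)
  list(pat = mat[, keep, drop = FALSE], weights = as.numeric(tab))
}

# Tip partial-likelihood matrices (k x npat per tip) for one pattern block
# with a fixed state alphabet `states` (character vector, length k).
tip_partials_for <- function(pat, states, missing_sym, dna = FALSE) {
  k <- length(states)
  lapply(seq_len(nrow(pat)), function(i) {
    m <- matrix(0, k, ncol(pat))
    for (p in seq_len(ncol(pat))) {
      s <- pat[i, p]
      if (s %in% missing_sym) {
        m[, p] <- 1
      } else if (dna) {
        m[match(IUPAC_DNA[[s]], states), p] <- 1
      } else {
        m[match(s, states), p] <- 1
      }
    }
    m
  })
}
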