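#' Canonical amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes, alphabetically ordered. This ordering
#' defines the index used by composition vectors and by the deterministic
#' tie-break ("alphabetical state order") of the parsimony machinery.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.MISSING_SYMBOLS <- c("-", "?", "X")
# ambiguity/rare codes mapped to missing with a warning (B/Z ambiguous,
# J = I/L, U = Sec, O = Pyl); the composition machinery cannot use them
.AMBIGUOUS_SYMBOLS <- c("B", "Z", "J", "U", "O")

#' Amino-acid alignment container
#'
#' Builds an `aa_alignment`: a taxa x positions character matrix over the
#' 20 canonical amino-acid codes, with `NA` marking missing cells. Input
#' symbols are normalized: lowercase is uppercased; `-`, `?` and `X` become
#' missing; the ambiguity codes B, Z, J, U, O are mapped to missing with a
#' warning. Any other symbol is an error naming the offending row and
#' column.
#'
#' @param x character matrix (rows = taxa) or list/character vector of
#'   equal-length sequence strings.
#' @param taxon_labels labels for the rows; defaults to existing
#'   rownames/names. Must be unique and non-empty.
#' @return An `aa_alignment` object (character matrix with class attribute;
#'   `NA` = missing).
#' @examples
#' aln <- aa_alignment(c(t1 = "ACDE", t2 = "AC-E"))
#' n_taxa(aln)
#' @export
aa_alignment <- function(x, taxon_labels = NULL) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(taxon_labels)) taxon_labels <- names(x)
    lens <- nchar(x)
    if (length(unique(lens)) > 1L)
      stop("alignment format error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    x <- do.call(rbind, lapply(unname(x), function(s)
      strsplit(s, "", fixed = TRUE)[[1]]))
  }
  if (!is.matrix(x)) stop("x must be a character matrix or sequence vector")
  if (is.null(taxon_labels)) taxon_labels <- rownames(x)
  if (is.null(taxon_labels) || any(!nzchar(taxon_labels)) ||
      anyNA(taxon_labels))
    stop("alignment format error: taxon labels missing or empty")
  taxon_labels <- as.character(taxon_labels)
  if (anyDuplicated(taxon_labels))
    stop("alignment format error: duplicate taxon labels: ",
         paste(unique(taxon_labels[duplicated(taxon_labels)]),
               collapse = ", "))
  if (length(taxon_labels) != nrow(x))
    stop("taxon_labels length does not match number of rows")

  m <- toupper(x)
  m[m %in% .MISSING_SYMBOLS] <- NA_character_
  amb <- !is.na(m) & m %in% .AMBIGUOUS_SYMBOLS
  if (any(amb)) {
    warning("mapped ", sum(amb), " ambiguity-code cell(s) (",
            paste(sort(unique(m[amb])), collapse = ", "),
            ") to missing")
    m[amb] <- NA_character_
  }
  bad <- !is.na(m) & !(m %in% AA_ALPHABET)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("alignment format error: illegal residue '", x[bad][1L],
         "' at row ", idx[1L], " (", taxon_labels[idx[1L]],
         "), column ", idx[2L])
  }
  dimnames(m) <- list(taxon_labels, NULL)
  class(m) <- c("aa_alignment", "matrix", "array")
  m
}

#' @rdname aa_alignment
#' @param aln an `aa_alignment`.
#' @export
n_taxa <- function(aln) nrow(aln)

#' @rdname aa_alignment
#' @export
n_columns <- function(aln) ncol(aln)

#' @rdname aa_alignment
#' @export
taxon_labels <- function(aln) rownames(aln)

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment: ", nrow(x), " taxa x ", ncol(x), " positions, ",
      sprintf("%.1f%%", 100 * mean(!is.na(x))), " data coverage\n", sep = "")
  invisible(x)
}

# integer-encoded view used by the parsimony engine: 1..20, NA = missing
.encode_alignment <- function(aln, alphabet = AA_ALPHABET) {
  m <- match(unclass(aln), alphabet)
  dim(m) <- dim(aln)
  dimnames(m) <- dimnames(aln)
  m
}

.subset_alignment <- function(aln, rows = NULL, cols = NULL) {
  m <- unclass(aln)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  class(m) <- c("aa_alignment", "matrix", "array")
  m
}

#' Read an alignment file
#'
#' Reads FASTA, relaxed sequential PHYLIP, or a NEXUS data block into a
#' normalized [aa_alignment]. Input taxon order is preserved.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`.
#' @return An [aa_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    stop("alignment format error: empty file: ", path)
  seqs <- switch(format,
    fasta = {
      x <- ape::read.FASTA(path, type = "AA")
      if (length(x) == 0L)
        stop("alignment format error: no sequences in ", path)
      labs <- names(x)
      if (anyDuplicated(labs))
        stop("alignment format error: duplicate taxon labels: ",
             paste(unique(labs[duplicated(labs)]), collapse = ", "))
      lens <- lengths(x)
      if (length(unique(lens)) > 1L)
        stop("alignment format error: ragged rows (lengths ",
             paste(unique(lens), collapse = ", "), ")")
      mat <- do.call(rbind, lapply(as.character(x), identity))
      rownames(mat) <- labs
      mat
    },
    phylip = .read_relaxed_phylip(path),
    nexus = {
      x <- ape::read.nexus.data(path)
      labs <- names(x)
      if (anyDuplicated(labs))
        stop("alignment format error: duplicate taxon labels: ",
             paste(unique(labs[duplicated(labs)]), collapse = ", "))
      lens <- lengths(x)
      if (length(unique(lens)) > 1L)
        stop("alignment format error: ragged rows")
      mat <- do.call(rbind, x)
      rownames(mat) <- labs
      mat
    })
  aa_alignment(seqs)
}

# relaxed PHYLIP, sequential: "ntax ncols" header, then one record per
# taxon: whitespace-separated label followed by the sequence (possibly
# wrapped over several lines)
.read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("alignment format error: truncated PHYLIP file")
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) < 2L || anyNA(hdr))
    stop("alignment format error: bad PHYLIP header: ", lines[1L])
  ntax <- hdr[1L]; ncols <- hdr[2L]
  body <- lines[-1L]
  labs <- character(ntax); seqs <- character(ntax)
  i <- 0L
  for (ln in body) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (i == 0L || nchar(seqs[i]) >= ncols) {
      i <- i + 1L
      if (i > ntax) stop("alignment format error: more records than header ntax")
      labs[i] <- parts[1L]
      seqs[i] <- paste(parts[-1L], collapse = "")
    } else {
      seqs[i] <- paste0(seqs[i], paste(parts, collapse = ""))
    }
  }
  if (i < ntax) stop("alignment format error: fewer records than header ntax")
  if (any(nchar(seqs) != ncols))
    stop("alignment format error: ragged rows (expected ", ncols,
         " columns, got ", paste(unique(nchar(seqs)), collapse = ", "), ")")
  names(seqs) <- labs
  if (anyDuplicated(labs))
    stop("alignment format error: duplicate taxon labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1L]]))
}

#' Write an alignment
#'
#' Writes FASTA (default) or relaxed sequential PHYLIP. Missing cells are
#' written as `-`.
#'
#' @param aln an [aa_alignment].
#' @param path output path.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  m <- unclass(aln)
  m[is.na(m)] <- "-"
  seqs <- apply(m, 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", seqs), con)
  } else {
    writeLines(paste(nrow(m), ncol(m)), con)
    writeLines(paste(names(seqs), seqs), con)
  }
  invisible(path)
}
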