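#' Amino-acid alignment objects
#'
#' An `aa_alignment` is a character matrix with one row per taxon and one
#' column per alignment site. Cells hold one of the 20 amino-acid one-letter
#' codes, the gap character `"-"`, or the ambiguity code `"X"`. Row names are
#' the (unique, whitespace-trimmed) taxon labels. All coordinates exposed to
#' the user are 1-based, matching R convention.
#'
#' @param x a character matrix (taxa x sites), or a named character vector of
#'   equal-length sequence strings.
#' @return an object of class `aa_alignment`.
#' @export
aa_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      bad <- names(x)[lens != lens[1L]][1L]
      stop("ragged alignment: sequence length of taxon '", bad,
           "' (", nchar(x[bad]), ") differs from '", names(x)[1L],
           "' (", lens[1L], ")")
    }
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
    x <- m
  }
  stopifnot(is.matrix(x), is.character(x))
  x[] <- toupper(x)
  x[x == "."] <- "-"
  x[x == "?"] <- "X"
  validate_alignment(x)
  structure(x, class = c("aa_alignment", class(x)))
}

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V","-","X")

validate_alignment <- function(m) {
  if (ncol(m) < 1L) stop("alignment must have at least one column")
  taxa <- rownames(m)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("all taxa must have non-empty labels")
  if (any(taxa != trimws(taxa)))
    stop("taxon labels must not have leading/trailing whitespace: ",
         paste(sQuote(taxa[taxa != trimws(taxa)]), collapse = ", "))
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  bad <- !(m %in% AA_ALPHABET)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1L, ]
    stop("illegal character '", m[idx[1L], idx[2L]], "' for taxon '",
         taxa[idx[1L]], "' at column ", idx[2L])
  }
  invisible(m)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", nrow(x), "taxa x", ncol(x), "sites\n")
  invisible(x)
}

n_sites <- function(aln) ncol(aln)
taxa_of <- function(aln) rownames(aln)

aln_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""),
                  rownames(aln))
}

#' Read a protein alignment
#'
#' Reads FASTA or relaxed PHYLIP (whitespace-delimited labels of any length;
#' sequential and interleaved layouts are both accepted). Lowercase input is
#' uppercased; `"."` is normalized to the gap `"-"` and `"?"` to the
#' ambiguity code `"X"`.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return an [aa_alignment].
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               set.attributes = FALSE)
    seqs <- vapply(recs, `[[`, character(1), 1L)
    names(seqs) <- trimws(names(recs))
    aa_alignment(seqs)
  } else {
    read_relaxed_phylip(path)
  }
}

# Relaxed PHYLIP: header "ntaxa nsites"; labels are whitespace-delimited
# tokens (no 10-character limit); sequence characters may be blank-separated.
# Sequential and interleaved layouts are auto-detected by line accounting.
read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a PHYLIP file (no sequence lines): ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]))
    stop("bad PHYLIP header: ", lines[1L])
  nt <- hdr[1L]; ns <- hdr[2L]
  body <- lines[-1L]
  taxa <- character(nt)
  seqs <- character(nt)
  # first block: each of the first nt lines starts with a label
  if (length(body) < nt) stop("PHYLIP file has fewer lines than taxa")
  for (i in seq_len(nt)) {
    toks <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    taxa[i] <- toks[1L]
    seqs[i] <- paste(toks[-1L], collapse = "")
  }
  rest <- body[-seq_len(nt)]
  # subsequent interleaved blocks carry sequence only (no labels)
  i <- 0L
  for (ln in rest) {
    i <- i %% nt + 1L
    seqs[i] <- paste0(seqs[i], gsub("\\s+", "", ln))
  }
  lens <- nchar(seqs)
  if (any(lens != ns)) {
    bad <- which(lens != ns)[1L]
    stop("PHYLIP sequence for taxon '", taxa[bad], "' has ", lens[bad],
         " characters, expected ", ns)
  }
  aa_alignment(stats::setNames(seqs, taxa))
}

#' Write a protein alignment
#'
#' FASTA or sequential relaxed PHYLIP output. Writing then reading back
#' reproduces the alignment exactly.
#'
#' @param aln an [aa_alignment].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  s <- aln_strings(aln)
  if (format == "fasta") {
    seqinr::write.fasta(as.list(unname(s)), names = names(s),
                        file.out = path, nbchar = 60)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(length(s), nchar(s[1L])), con)
    writeLines(paste(names(s), s), con)
  }
  invisible(path)
}

#' Remove gappy and ambiguous columns
#'
#' Drops every column whose gap fraction exceeds `max_gap_fraction` and,
#' if `drop_ambiguous`, every column containing the ambiguity code `"X"`.
#' This is the package's reproducible surrogate for by-eye removal of
#' ambiguously aligned sites; both knobs are exposed in the run
#' configuration.
#'
#' @param aln an [aa_alignment].
#' @param max_gap_fraction columns with a strictly greater proportion of
#'   gaps are removed (default 0.5).
#' @param drop_ambiguous drop columns containing `"X"` (default TRUE).
#' @return a list with elements `alignment` (the reduced [aa_alignment]) and
#'   `mask` (integer vector of retained original 1-based column indices).
#' @export
mask_columns <- function(aln, max_gap_fraction = 0.5, drop_ambiguous = TRUE) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- unclass(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  if (drop_ambiguous) keep <- keep & colSums(m == "X") == 0L
  if (!any(keep))
    stop("masking removed all ", ncol(m), " columns; raise max_gap_fraction",
         " or disable drop_ambiguous")
  list(alignment = aa_alignment(m[, keep, drop = FALSE]),
       mask = which(keep))
}

#' Export a column mask as TSV
#'
#' Two columns: `kept_index` (position in the masked alignment) and
#' `original_index` (position in the input alignment), both 1-based.
#' @param mask integer vector as returned by [mask_columns()].
#' @param path output path.
#' @export
write_column_mask <- function(mask, path) {
  utils::write.table(
    data.frame(kept_index = seq_along(mask), original_index = mask),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map alignment columns to reference-sequence positions
#'
#' Column `i` maps to the (1-based) count of non-gap reference residues in
#' columns `1..i` when the reference taxon has a residue at `i`, and to `NA`
#' where the reference is gapped. This reproduces the convention of
#' numbering alignment features by the residue positions of a designated
#' reference protein.
#'
#' @param aln an [aa_alignment].
#' @param ref_taxon taxon label of the reference row.
#' @return integer vector of length `ncol(aln)` with `NA` at reference gaps.
#' @export
map_to_reference <- function(aln, ref_taxon) {
  if (!ref_taxon %in% rownames(aln))
    stop("unknown reference taxon: ", ref_taxon)
  ref <- unclass(aln)[ref_taxon, ]
  res <- ifelse(ref == "-", NA_integer_, cumsum(ref != "-"))
  as.integer(res)
}
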