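#' Read and write dot-bracket documents
#'
#' The dot-bracket ("db") exchange format stores each molecule as a triplet of
#' lines: a header starting with `>`, the sequence, and a structure line of
#' equal length. Four bracket alphabets `()`, `[]`, `{}`, `<>` encode up to
#' four pseudoknot layers; `.` marks unpaired positions.
#'
#' @param text character vector of lines, or a length-1 string containing the
#'   whole document; alternatively use `file`.
#' @param file path to a dot-bracket file.
#' @return `parse_dotbracket()`: a named list of [rna_structure] objects.
#' @export
parse_dotbracket <- function(text = NULL, file = NULL) {
  lines <- read_lines_arg(text, file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("dot-bracket document must consist of (header, sequence, structure) triplets")
  n <- length(lines) %/% 3L
  out <- vector("list", n)
  for (k in seq_len(n)) {
    hdr <- lines[3L * k - 2L]
    seq <- trimws(lines[3L * k - 1L])
    db  <- trimws(lines[3L * k])
    if (!startsWith(hdr, ">"))
      stop("expected header line starting with '>', got: ", hdr)
    name <- trimws(sub("^>", "", hdr))
    if (nchar(seq) != nchar(db))
      stop("sequence/structure length mismatch for record ", name)
    out[[k]] <- rna_structure(name, seq, dotbracket_to_pairs(db))
  }
  names(out) <- vapply(out, function(s) s$name, character(1L))
  out
}

dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  legal <- c(".", bracket_open, bracket_close)
  bad <- setdiff(unique(ch), legal)
  if (length(bad))
    stop("illegal structure characters: ", paste(bad, collapse = ", "))
  pairs <- matrix(integer(0), ncol = 2L)
  for (l in seq_along(bracket_open)) {
    stack <- integer(0)
    for (pos in seq_along(ch)) {
      if (ch[pos] == bracket_open[l]) {
        stack <- c(stack, pos)
      } else if (ch[pos] == bracket_close[l]) {
        if (!length(stack))
          stop("unbalanced '", bracket_close[l], "' at position ", pos)
        pairs <- rbind(pairs, c(stack[length(stack)], pos))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unmatched '", bracket_open[l], "' at position ",
           stack[length(stack)])
  }
  pairs
}

#' @rdname parse_dotbracket
#' @param structures a list of [rna_structure] objects (or a single one).
#' @param path output file; when `NULL` the lines are returned invisibly.
#' @export
write_dotbracket <- function(structures, path = NULL) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  lines <- unlist(lapply(structures, function(s) {
    c(paste0(">", s$name), s$sequence, dotbracket_string(s))
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read and write CT (connectivity table) files
#'
#' Standard Zuker-style CT: a header line whose first field is the sequence
#' length, then one row per residue with columns
#' `index base previous next pair index`. The pair column is 1-based with 0
#' meaning unpaired; reciprocity of the pairing column is enforced.
#'
#' @inheritParams parse_dotbracket
#' @return `parse_ct()`: an [rna_structure].
#' @export
parse_ct <- function(text = NULL, file = NULL) {
  lines <- read_lines_arg(text, file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty CT document")
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  L <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(L)) stop("CT header must start with the sequence length")
  name <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else "ct"
  rows <- lines[-1L]
  if (length(rows) != L)
    stop("CT declares length ", L, " but has ", length(rows), " rows")
  fields <- lapply(rows, function(r) strsplit(trimws(r), "\\s+")[[1L]])
  base <- vapply(fields, `[`, character(1L), 2L)
  paircol <- as.integer(vapply(fields, `[`, character(1L), 5L))
  if (anyNA(paircol) || any(paircol < 0L) || any(paircol > L))
    stop("CT pair column out of range")
  # reciprocity
  paired <- which(paircol > 0L)
  for (i in paired) {
    if (paircol[paircol[i]] != i)
      stop("non-reciprocal CT pairing: row ", i, " says ", paircol[i],
           " but row ", paircol[i], " says ", paircol[paircol[i]])
  }
  ij <- cbind(paired, paircol[paired])
  ij <- ij[ij[, 1L] < ij[, 2L], , drop = FALSE]
  rna_structure(name, paste(base, collapse = ""), ij)
}

#' @rdname parse_ct
#' @param s an [rna_structure].
#' @param path output file; when `NULL` the lines are returned invisibly.
#' @export
write_ct <- function(s, path = NULL) {
  stopifnot(inherits(s, "rna_structure"))
  L <- nchar(s$sequence)
  partner <- partner_vector(s)
  partner[is.na(partner)] <- 0L
  base <- strsplit(s$sequence, "")[[1L]]
  lines <- c(
    paste(L, s$name),
    sprintf("%d %s %d %d %d %d", seq_len(L), base, seq_len(L) - 1L,
            c(seq_len(L - 1L) + 1L, 0L), partner, seq_len(L))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read and write plain FASTA sequence files
#'
#' FASTA support for bare RNA sequences, backed by Biostrings; `T` is
#' converted to `U` on read.
#'
#' @param file path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readBStringSet(file)
  seqs <- vapply(as.character(set), normalize_sequence, character(1L))
  names(seqs) <- trimws(vapply(strsplit(names(set), "\\s+"), `[`,
                               character(1L), 1L))
  seqs
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

read_lines_arg <- function(text, file) {
  if (!is.null(file)) return(readLines(file))
  if (is.null(text)) stop("supply either text or file")
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n")[[1L]]
  text
}

#' Read and write per-base reactivity tables
#'
#' The reactivity CSV carries one row per reference base with columns
#' `reference, position, base, coverage, mutations, reactivity, normalized`
#' (position 1-based). Masked entries carry the sentinel value (-1000 by
#' default) literally in the `reactivity`/`normalized` columns.
#'
#' @param file path to a CSV file.
#' @return `read_reactivity_csv()`: a named list of [probed_record] objects
#'   (one replicate each; rows of the same reference are grouped by position).
#' @export
read_reactivity_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("reference", "position", "base", "coverage", "mutations",
            "reactivity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reactivity CSV missing columns: ", paste(miss, collapse = ", "))
  if (!"normalized" %in% names(df)) df$normalized <- NA_real_
  recs <- lapply(split(df, df$reference), function(d) {
    d <- d[order(d$position), ]
    seq <- paste(d$base, collapse = "")
    prof <- reactivity_profile(coverage = d$coverage, mutations = d$mutations,
                               reactivity = d$reactivity,
                               normalized = d$normalized)
    probed_record(d$reference[1L], seq, list(prof))
  })
  recs
}

#' @rdname read_reactivity_csv
#' @param records list of [probed_record] objects; the merged profile is
#'   written when present, otherwise the first replicate.
#' @param path output CSV path.
#' @export
write_reactivity_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    p <- if (!is.null(r$merged)) r$merged else r$replicates[[1L]]
    data.frame(reference = r$name,
               position = seq_len(nchar(r$sequence)),
               base = strsplit(r$sequence, "")[[1L]],
               coverage = p$coverage,
               mutations = p$mutations,
               reactivity = p$reactivity,
               normalized = if (is.null(p$normalized)) NA_real_ else p$normalized,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
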