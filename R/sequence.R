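# Protein sequence container and FASTA / tabular I/O.

#' Protein sequence objects
#'
#' A validated one-letter amino-acid sequence with an identifier and
#' optional terminal-blocking flags. Blocking a terminus (N-terminal
#' acetylation, C-terminal amidation, or a terminus absent from a construct)
#' removes its ionizable group from the charge calculation, which can shift
#' the isoelectric point of short peptides appreciably.
#'
#' @param residues Character string of one-letter codes (or a character
#'   vector of single letters).
#' @param id Sequence identifier (non-empty string).
#' @param nterm_blocked,cterm_blocked Logical; `TRUE` marks the terminus as
#'   chemically blocked (no titratable terminal group). Default free termini.
#' @param allow_x Permit the ambiguity code `X` (handled downstream by
#'   [residue_lipophilicity()]); all other non-standard codes are rejected.
#' @return An object of class `"protein"` with fields `id`, `residues`,
#'   `nterm_blocked`, `cterm_blocked`.
#' @examples
#' p <- protein("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", id = "IAPP")
#' p
#' @export
protein <- function(residues, id = "seq", nterm_blocked = FALSE,
                    cterm_blocked = FALSE, allow_x = FALSE) {
  if (length(residues) > 1) residues <- paste(residues, collapse = "")
  stopifnot(is.character(residues), length(residues) == 1)
  if (!nzchar(id)) stop("protein id must be non-empty")
  if (nchar(residues) < 1) stop("protein sequence must have length >= 1")
  aa <- strsplit(residues, "")[[1]]
  bad <- which(!aa %in% c(AA20, if (allow_x) "X"))
  if (length(bad) > 0) {
    stop("invalid residue code '", aa[bad[1]], "' at position ", bad[1],
         " in sequence '", id, "'")
  }
  structure(list(id = id, residues = residues,
                 nterm_blocked = isTRUE(nterm_blocked),
                 cterm_blocked = isTRUE(cterm_blocked)),
            class = "protein")
}

#' @export
print.protein <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<protein> %s (%d aa%s%s)\n  %s\n", x$id, n,
              if (x$nterm_blocked) ", N-term blocked" else "",
              if (x$cterm_blocked) ", C-term blocked" else "",
              shown))
  invisible(x)
}

as_protein <- function(x, id = "seq") {
  if (inherits(x, "protein")) return(x)
  if (is.character(x) && length(x) == 1) return(protein(x, id = id))
  stop("expected a protein object or a single sequence string")
}

residue_vector <- function(p) strsplit(p$residues, "")[[1]]

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file into a list of [protein()]
#' objects, preserving record order. Construct chemistry can be annotated in
#' the description line with the tags `nterm_blocked` and/or
#' `cterm_blocked`, e.g. `>CRF corticotropin cterm_blocked`.
#'
#' Under the `"strict"` policy any character outside the 20 standard
#' uppercase codes raises an error naming the record and position, and
#' duplicate identifiers are rejected. Under `"lenient"` sequences are
#' uppercased and whitespace and the stop characters `*` and `.` are
#' stripped before validation.
#'
#' @param path Path to a FASTA file.
#' @param policy `"strict"` (default) or `"lenient"`.
#' @return Named list of `"protein"` objects (names are the record ids).
#' @export
read_fasta <- function(path, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("cannot read '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(lines) == 0 || length(headers) == 0) {
    stop("'", path, "' contains no FASTA records")
  }
  if (headers[1] != 1) stop("'", path, "' does not start with a '>' header")
  starts <- headers + 1
  ends <- c(headers[-1] - 1, length(lines))
  out <- vector("list", length(headers))
  ids <- character(length(headers))
  for (i in seq_along(headers)) {
    header <- sub("^>", "", lines[headers[i]])
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    if (!nzchar(id)) stop("record ", i, " in '", path, "' has an empty id")
    seq <- if (starts[i] > ends[i]) "" else
      paste(lines[starts[i]:ends[i]], collapse = "")
    if (policy == "lenient") {
      seq <- toupper(gsub("[[:space:]*.]", "", seq))
    }
    if (!nzchar(seq)) stop("record '", id, "' in '", path, "' is empty")
    out[[i]] <- protein(seq, id = id,
                        nterm_blocked = grepl("\\bnterm_blocked\\b", desc),
                        cterm_blocked = grepl("\\bcterm_blocked\\b", desc))
    ids[i] <- id
  }
  if (policy == "strict" && anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' Terminal-blocking flags are serialized as description tags so that
#' [read_fasta()] round-trips them.
#'
#' @param x A `"protein"` or a list of them.
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  if (inherits(x, "protein")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in x) {
    tags <- c(if (p$nterm_blocked) "nterm_blocked",
              if (p$cterm_blocked) "cterm_blocked")
    writeLines(paste0(">", p$id,
                      if (length(tags)) paste0(" ", paste(tags, collapse = " "))
                      else ""), con)
    s <- p$residues
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a profile or solubility curve as CSV
#'
#' One row per profile position or per pH grid point, with a header line.
#' Numbers are written in full double precision with `.` as the decimal
#' separator, so a re-read with [utils::read.csv()] reproduces the values.
#'
#' @param x A data frame result ([lipophilicity_profile()], [ph_sweep()],
#'   [residue_solubility_profile()], or any data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path) {
  stopifnot(is.data.frame(x), nrow(x) > 0)
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
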