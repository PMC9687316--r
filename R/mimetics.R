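#' Parse an interfacial residue list
#'
#' Parses the compact text notation used to print interfacial residue
#' stretches: comma-separated tokens of the form `K82` (one-letter code plus
#' author residue number), `R-185` (hyphen variant, equivalent), `ILE210`
#' (three-letter variant) or `X` (a single missing residue, which takes the
#' number previous + 1). Numbers must be strictly increasing; in lenient
#' mode a token breaking monotonicity is repaired to previous + 1 and
#' flagged (`repaired`), in strict mode it is an error.
#'
#' @param text the residue list, e.g. `"K82, N83, X, F85"`. May span
#'   multiple lines.
#' @param source identifier of the source protein, kept as an attribute.
#' @param lenient repair non-monotonic numbers instead of failing.
#' @return `data.frame` with columns `aa` (one-letter code or `"X"`),
#'   `resno`, `gap` (logical), `repaired` (logical); attribute `source`.
#' @examples
#' parseResidueList("K82, N83, X, F85")
#' @export
parseResidueList <- function(text, source = "", lenient = FALSE) {
  tokens <- unlist(strsplit(paste(text, collapse = ","), "[,\n]"))
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  n <- length(tokens)
  out <- data.frame(aa = character(n), resno = integer(n),
                    gap = logical(n), repaired = logical(n),
                    stringsAsFactors = FALSE)
  prev <- NA_integer_
  for (i in seq_len(n)) {
    tok <- tokens[i]
    if (toupper(tok) == "X") {
      if (is.na(prev))
        stop("gap marker 'X' cannot open a residue list")
      out$aa[i] <- "X"
      out$resno[i] <- prev + 1L
      out$gap[i] <- TRUE
    } else {
      m <- regmatches(tok, regexec("^([A-Za-z]{1,3})[- ]?([0-9]+)$", tok))[[1]]
      if (length(m) != 3L)
        stop("unknown residue token: '", tok, "'")
      aa <- toupper(m[2])
      if (nchar(aa) == 3L) {
        aa <- aaThreeToOne(aa)
        if (aa == "X") stop("unknown residue code in token: '", tok, "'")
      } else if (nchar(aa) != 1L || !aa %in% names(.AA1TO3)) {
        stop("unknown residue code in token: '", tok, "'")
      }
      num <- as.integer(m[3])
      if (!is.na(prev) && num <= prev) {
        if (!lenient)
          stop("residue numbers not strictly increasing at token '", tok,
               "' (previous ", prev, ")")
        num <- prev + 1L
        out$repaired[i] <- TRUE
      }
      out$aa[i] <- aa
      out$resno[i] <- num
    }
    prev <- out$resno[i]
  }
  attr(out, "source") <- source
  out
}

#' Read blocks of interfacial residue lists from a text file
#'
#' File format: lines starting `#` are comments, a line `> NAME` opens the
#' block for source protein NAME, and every following non-empty line is a
#' comma-separated residue list appended to that block. All lines of a block
#' are concatenated into one ordered residue list per source protein.
#'
#' @param path file path (or a character vector of lines).
#' @param lenient passed to [parseResidueList()]; defaults to `TRUE` since
#'   printed tables occasionally carry a typo in a residue number.
#' @return named list of residue-list `data.frame`s, in file order.
#' @seealso [extractStretches()], [selectPeptides()]
#' @export
readResidueLists <- function(path, lenient = TRUE) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  current <- NULL
  buf <- character(0)
  flush <- function() {
    if (!is.null(current) && length(buf))
      out[[current]] <<- parseResidueList(paste(buf, collapse = ", "),
                                          source = current,
                                          lenient = lenient)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      current <- trimws(sub("^>", "", ln))
      buf <- character(0)
    } else {
      if (is.null(current)) stop("residue list line before any '>' header")
      buf <- c(buf, ln)
    }
  }
  flush()
  out
}

#' Maximal residue stretches with isolated single-residue gaps
#'
#' Scans an interfacial residue list for maximal runs in which consecutive
#' present residues are separated by at most one missing residue. Any number
#' of such single-residue gaps may occur inside one stretch, but two or more
#' consecutive missing residues terminate it; stretches begin and end on
#' present residues. This is the selection rule behind glycine-bridged
#' interface peptides: one absent residue is tolerated (later bridged by G),
#' a longer break is not.
#'
#' @param list a residue list from [parseResidueList()] /
#'   [readResidueLists()].
#' @return `data.frame` with one row per stretch: `source`, `start`, `end`,
#'   `length` (positions spanned, `end - start + 1`), `ngaps`, `gaps`
#'   (comma-joined missing residue numbers, `""` if none).
#' @export
extractStretches <- function(list) {
  src <- attr(list, "source")
  if (is.null(src)) src <- ""
  present <- sort(unique(list$resno[list$aa != "X"]))
  rows <- list()
  if (length(present)) {
    start <- present[1]
    prev <- present[1]
    gaps <- integer(0)
    close_stretch <- function(start, end, gaps)
      data.frame(source = src, start = start, end = end,
                 length = end - start + 1L, ngaps = length(gaps),
                 gaps = paste(gaps, collapse = ","),
                 stringsAsFactors = FALSE)
    for (p in present[-1]) {
      d <- p - prev
      if (d == 1L) {
        prev <- p
      } else if (d == 2L) {
        gaps <- c(gaps, prev + 1L)
        prev <- p
      } else {
        rows[[length(rows) + 1L]] <- close_stretch(start, prev, gaps)
        start <- p
        prev <- p
        gaps <- integer(0)
      }
    }
    rows[[length(rows) + 1L]] <- close_stretch(start, prev, gaps)
  }
  if (!length(rows))
    return(data.frame(source = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      ngaps = integer(0), gaps = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Build the glycine-bridged peptide of a stretch
#'
#' Walks the stretch positions in order, taking the one-letter code of each
#' present residue and a glycine (G) at each bridged gap.
#'
#' @param stretch one row of [extractStretches()] output (or a list with
#'   `start` and `end`).
#' @param list the residue list the stretch came from.
#' @return the peptide sequence (one-letter string).
#' @examples
#' rl <- parseResidueList("K82, N83, X, F85, Y86, W87, X, Q89, N90")
#' s <- extractStretches(rl)
#' buildPeptide(s[1, ], rl)  # "KNGFYWGQN"
#' @export
buildPeptide <- function(stretch, list) {
  span <- seq(stretch$start, stretch$end)
  aa <- list$aa[match(span, list$resno)]
  aa[is.na(aa) | aa == "X"] <- "G"
  paste(aa, collapse = "")
}

#' Select peptide candidates from interfacial residue lists
#'
#' Extracts all maximal single-gap stretches from every residue list, builds
#' the glycine-bridged sequences, keeps those spanning at least `minLen`
#' positions, and assigns ids `P1..Pn` in input order (pass the lists with
#' the receptor's fragment-1 complexes first to follow the usual ordering
#' convention), then by position within a list.
#'
#' @param lists a named list of residue lists ([readResidueLists()] output),
#'   or a single residue list.
#' @param minLen minimum stretch length (positions spanned); default 8.
#' @return `data.frame` with `id`, `source`, `start`, `end`, `length`,
#'   `ngaps`, `gaps`, `sequence`. Zero rows when nothing qualifies.
#' @export
selectPeptides <- function(lists, minLen = 8) {
  if (is.data.frame(lists)) lists <- list(lists)
  rows <- list()
  for (rl in lists) {
    st <- extractStretches(rl)
    if (!nrow(st)) next
    st <- st[st$length >= minLen, , drop = FALSE]
    if (!nrow(st)) next
    st$sequence <- vapply(seq_len(nrow(st)), function(i)
      buildPeptide(st[i, ], rl), character(1))
    rows[[length(rows) + 1L]] <- st
  }
  if (!length(rows)) {
    out <- data.frame(id = character(0), source = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), ngaps = integer(0),
                      gaps = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- cbind(id = paste0("P", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write peptide candidates as FASTA
#'
#' Headers follow `id|source|start-end|gaps`.
#'
#' @param peptides [selectPeptides()] output.
#' @param file output path.
#' @return the `AAStringSet`, invisibly.
#' @export
peptidesToFasta <- function(peptides, file) {
  headers <- sprintf("%s|%s|%d-%d|%s", peptides$id, peptides$source,
                     peptides$start, peptides$end,
                     ifelse(nzchar(peptides$gaps), peptides$gaps, "-"))
  set <- Biostrings::AAStringSet(stats::setNames(peptides$sequence, headers))
  Biostrings::writeXStringSet(set, file)
  invisible(set)
}

#' DNA-binding site ranges
#'
#' The receptor's DNA-binding residue ranges used for overlap scoring; the
#' bundled default ties range 210--276 to fragment 1 and 312--370 to
#' fragment 2, and can be overridden per run.
#'
#' @return `data.frame` with `fragment`, `start`, `end`.
#' @export
dnaBindingSites <- function() {
  cfg <- read_config_json("dna_binding_sites.json")
  as.data.frame(cfg$sites, stringsAsFactors = FALSE)
}

#' Overlap of interface residues with a DNA-binding site
#'
#' Counts the receptor-side interface residues whose author number falls
#' inside the site range (inclusive).
#'
#' @param residues integer residue numbers of the receptor-side interface
#'   (or a `data.frame` with a `resno` column).
#' @param site `c(start, end)`, a list with `start`/`end`, or one row of
#'   [dnaBindingSites()].
#' @return list with `count` and the sorted `residues` inside the range.
#' @examples
#' overlapScore(c(208, 215, 300), c(210, 276))$count  # 1
#' @export
overlapScore <- function(residues, site) {
  if (is.data.frame(residues)) residues <- residues$resno
  residues <- sort(unique(as.integer(residues)))
  if (is.list(site) || is.data.frame(site)) {
    lo <- as.integer(site$start)
    hi <- as.integer(site$end)
  } else {
    lo <- as.integer(site[1])
    hi <- as.integer(site[2])
  }
  if (is.na(lo) || is.na(hi) || lo > hi) stop("malformed site range")
  inside <- residues[residues >= lo & residues <= hi]
  list(count = length(inside), residues = inside)
}

#' Parse a plain residue-token list (no gap markers)
#'
#' Convenience for printed interface-residue lists such as
#' `"ILE210, TYR211, LEU246"`: returns codes and numbers without the
#' monotonicity rules of [parseResidueList()].
#'
#' @param text tokens separated by commas, semicolons or whitespace.
#' @return `data.frame` with `aa` (one-letter) and `resno`.
#' @export
parseResidueTokens <- function(text) {
  tokens <- unlist(strsplit(paste(text, collapse = " "), "[,;[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  m <- regmatches(tokens, regexec("^([A-Za-z]{1,3})[- ]?([0-9]+)$", tokens))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad)) stop("unknown residue token: '", tokens[bad[1]], "'")
  aa <- vapply(m, `[[`, character(1), 2)
  aa <- ifelse(nchar(aa) == 3L, aaThreeToOne(aa), toupper(aa))
  data.frame(aa = aa,
             resno = as.integer(vapply(m, `[[`, character(1), 3)),
             stringsAsFactors = FALSE)
}
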