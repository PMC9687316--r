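#' Per-residue confidence track of a predicted structure
#'
#' Predicted models carry a per-residue confidence score (0--100) in the
#' B-factor column of every atom. The track is the mean of the atom values
#' per residue, which equals the score itself when, as usual, all atoms of a
#' residue share one value, and stays robust for mixed inputs.
#'
#' @param structure a [ProteinStructure-class] whose atoms carry confidence
#'   in `bscore`.
#' @return `data.frame` with columns `chain`, `resno`, `icode`, `resname`,
#'   `score`, one row per residue in structure order.
#' @examples
#' s <- makeConfidenceTrack(seed = 1, chainLength = 20,
#'                          segments = list(c(5, 10)))
#' head(confidenceTrack(s$structure))
#' @export
confidenceTrack <- function(structure) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- atoms(structure)
  key <- factor(.residue_key(a), levels = unique(.residue_key(a)))
  score <- as.numeric(tapply(a$bscore, key, mean))
  out <- cbind(residueTable(structure), score = score)
  if (any(out$score < 0 | out$score > 100))
    warning("confidence scores outside [0, 100]")
  out
}

#' Extract high-confidence fragments from a confidence track
#'
#' Finds maximal runs of consecutive residues whose confidence exceeds
#' `threshold` (strict `>` by default, as the usual ">90" rule is printed),
#' then groups runs separated by at most `mergeGap` low-confidence residues
#' into one multi-run fragment; a larger gap starts a new fragment. With the
#' defaults, a predicted structure whose high-confidence runs are separated
#' by gaps of up to 15 residues yields one fragment per confident region,
#' reproducing the two-fragment split used to prepare docking receptors.
#'
#' @param track a confidence track from [confidenceTrack()], or a
#'   [ProteinStructure-class] (converted internally).
#' @param threshold confidence cutoff; residues with `score > threshold`
#'   qualify. Default 90. Set `inclusive = TRUE` for `>=`.
#' @param mergeGap maximum number of consecutive low-confidence residues
#'   allowed inside one fragment. Default 15.
#' @param inclusive logical; use `>=` instead of `>`.
#' @return list of fragment specs; each is `list(fragment_id, chain, runs)`
#'   with `runs` a list of inclusive `c(start, end)` residue-number
#'   intervals, ordered by first residue. Empty list when nothing qualifies.
#' @seealso [carveFragment()], [writeFragments()]
#' @export
extractConfidentFragments <- function(track, threshold = 90, mergeGap = 15,
                                      inclusive = FALSE) {
  if (is(track, "ProteinStructure")) track <- confidenceTrack(track)
  stopifnot(is.data.frame(track),
            all(c("chain", "resno", "score") %in% names(track)))
  frags <- list()
  for (ch in unique(track$chain)) {
    tr <- track[track$chain == ch, , drop = FALSE]
    tr <- tr[order(tr$resno), , drop = FALSE]
    hi <- if (inclusive) tr$score >= threshold else tr$score > threshold
    runs <- residue_runs(tr$resno[hi])
    if (!length(runs)) next
    # group runs whose separating gap (in residue numbering) is <= mergeGap
    group <- list(runs[[1]])
    for (r in runs[-1]) {
      gap <- r[1] - group[[length(group)]][2] - 1L
      if (gap <= mergeGap) {
        group[[length(group) + 1L]] <- r
      } else {
        frags[[length(frags) + 1L]] <- list(chain = ch, runs = group)
        group <- list(r)
      }
    }
    frags[[length(frags) + 1L]] <- list(chain = ch, runs = group)
  }
  lapply(seq_along(frags), function(i)
    list(fragment_id = paste0("fragment", i), chain = frags[[i]]$chain,
         runs = frags[[i]]$runs))
}

# maximal runs of consecutive integers; returns list of c(start, end)
residue_runs <- function(numbers) {
  if (!length(numbers)) return(list())
  numbers <- sort(unique(as.integer(numbers)))
  breaks <- which(diff(numbers) != 1L)
  starts <- numbers[c(1L, breaks + 1L)]
  ends <- numbers[c(breaks, length(numbers))]
  mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
}

#' Carve a fragment out of a structure
#'
#' Returns a new structure containing exactly the residues listed in the
#' fragment's run intervals, coordinates untouched. Used to cut the
#' high-confidence fragments out of a full-length predicted model before
#' docking.
#'
#' @param structure a [ProteinStructure-class].
#' @param spec a fragment spec (`list(fragment_id, chain, runs)`) as
#'   produced by [extractConfidentFragments()], or a bare list of
#'   `c(start, end)` intervals (then `chain` must be given).
#' @param chain chain id when `spec` is a bare run list.
#' @return a [ProteinStructure-class] restricted to the runs.
#' @export
carveFragment <- function(structure, spec, chain = NULL) {
  stopifnot(is(structure, "ProteinStructure"))
  if (is.list(spec) && !is.null(spec$runs)) {
    runs <- spec$runs
    chain <- spec$chain
    fid <- spec$fragment_id
  } else {
    runs <- spec
    fid <- "fragment"
    if (is.null(chain)) stop("chain must be given with a bare run list")
  }
  a <- atoms(structure)
  keep <- rep(FALSE, nrow(a))
  for (r in runs) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] > r[2])
      stop("malformed run interval: ", paste(r, collapse = "-"))
    hit <- a$chain == chain & a$resno >= r[1] & a$resno <= r[2]
    present <- unique(a$resno[hit])
    missing <- setdiff(seq(r[1], r[2]), present)
    if (length(missing))
      stop(sprintf("run %d-%d refers to residues absent from chain %s: %s",
                   r[1], r[2], chain,
                   paste(utils::head(missing, 5), collapse = ", ")))
    keep <- keep | hit
  }
  new("ProteinStructure", id = paste(structure@id, fid, sep = "_"),
      atoms = {
        out <- a[keep, , drop = FALSE]
        rownames(out) <- NULL
        out
      },
      title = structure@title)
}

#' Serialize fragment specs as JSON
#'
#' Fragment specs are exchanged as
#' `{"fragment_id": ..., "chain": ..., "runs": [[start, end], ...]}`.
#'
#' @param fragments list of fragment specs.
#' @param file optional output path.
#' @return JSON string (invisibly when `file` is given).
#' @export
writeFragments <- function(fragments, file = NULL) {
  payload <- lapply(fragments, function(f)
    list(fragment_id = f$fragment_id, chain = f$chain,
         runs = lapply(f$runs, as.integer)))
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname writeFragments
#' @param x JSON text or path for `readFragments`.
#' @export
readFragments <- function(x) {
  obj <- jsonlite::read_json(x, simplifyVector = FALSE)
  lapply(obj, function(f)
    list(fragment_id = f$fragment_id, chain = f$chain,
         runs = lapply(f$runs, function(r) as.integer(unlist(r)))))
}
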