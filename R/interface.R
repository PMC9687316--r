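#' Residue character classification
#'
#' One-letter amino-acid code to `charged`/`polar`/`apolar` mapping, as used
#' to classify interfacial contacts. The bundled scheme (config file
#' `residue_classes.json`) takes D, E, K, R as charged and splits the rest
#' polar/apolar following the contact-based affinity model the weights ship
#' with; it is data, not a constant, and can be edited per run.
#'
#' @return named character vector over the 20 standard residues.
#' @export
defaultResidueClasses <- function() {
  cfg <- read_config_json("residue_classes.json")
  unlist(cfg$classes)
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.AA1TO3 <- stats::setNames(names(.AA3TO1), .AA3TO1)

#' @rdname defaultResidueClasses
#' @param code three-letter residue codes.
#' @export
aaThreeToOne <- function(code) {
  out <- .AA3TO1[toupper(code)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Classified interfacial contacts at a distance threshold
#'
#' A residue pair (one residue per side) is a contact when any heavy-atom
#' pair distance is `<=` threshold (5.5 Angstrom default, the convention of
#' contact-based affinity models). Hydrogens are ignored; each contacting
#' residue pair is counted once and classified by the character
#' (charged/polar/apolar) of its two residues.
#'
#' @inheritParams deltaSASA
#' @param scheme residue classification, see [defaultResidueClasses()].
#' @param threshold contact distance, Angstrom.
#' @return a [ContactTable-class].
#' @export
interfacialContacts <- function(complexed, receptorChains, ligandChains,
                                scheme = defaultResidueClasses(),
                                threshold = 5.5) {
  split_chains_check(complexed, receptorChains, ligandChains)
  a <- atoms(complexed)
  a <- a[a$element != "H", , drop = FALSE]  # heavy atoms only
  ar <- a[a$chain %in% receptorChains, , drop = FALSE]
  al <- a[a$chain %in% ligandChains, , drop = FALSE]
  pairs <- empty_contact_pairs()
  if (nrow(ar) && nrow(al)) {
    xr <- as.matrix(ar[, c("x", "y", "z")])
    xl <- as.matrix(al[, c("x", "y", "z")])
    d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * xr %*% t(xl)
    hit <- which(d2 <= threshold^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      df <- data.frame(
        chainR = ar$chain[hit[, 1]], resnoR = ar$resno[hit[, 1]],
        icodeR = ar$icode[hit[, 1]], resnameR = ar$resname[hit[, 1]],
        chainL = al$chain[hit[, 2]], resnoL = al$resno[hit[, 2]],
        icodeL = al$icode[hit[, 2]], resnameL = al$resname[hit[, 2]],
        dist = sqrt(pmax(d2[hit], 0)), stringsAsFactors = FALSE)
      key <- paste(df$chainR, df$resnoR, df$icodeR,
                   df$chainL, df$resnoL, df$icodeL, sep = "\r")
      ord <- order(factor(key, levels = unique(key)), df$dist)
      df <- df[ord, ]
      pairs <- df[!duplicated(paste(df$chainR, df$resnoR, df$icodeR,
                                    df$chainL, df$resnoL, df$icodeL,
                                    sep = "\r")), , drop = FALSE]
      names(pairs)[names(pairs) == "dist"] <- "minDist"
      pairs$classR <- unname(scheme[aaThreeToOne(pairs$resnameR)])
      pairs$classL <- unname(scheme[aaThreeToOne(pairs$resnameL)])
      if (anyNA(pairs$classR) || anyNA(pairs$classL))
        stop("classification scheme does not cover all contact residues")
      rownames(pairs) <- NULL
    }
  }
  counts <- c(cc = 0, cp = 0, ca = 0, pp = 0, pa = 0, aa = 0)
  if (nrow(pairs)) {
    abbr <- c(charged = "c", polar = "p", apolar = "a")
    k <- vapply(seq_len(nrow(pairs)), function(i) {
      two <- sort(c(abbr[[pairs$classR[i]]], abbr[[pairs$classL[i]]]))
      paste0(two[1], two[2])
    }, character(1))
    k[k == "ap"] <- "pa"  # unordered pair naming: cc, cp, ca, pp, pa, aa
    k[k == "ac"] <- "ca"
    tab <- table(k)
    counts[names(tab)] <- as.numeric(tab)
  }
  new("ContactTable", pairs = pairs, counts = counts, threshold = threshold)
}

empty_contact_pairs <- function() {
  data.frame(chainR = character(0), resnoR = integer(0),
             icodeR = character(0), resnameR = character(0),
             chainL = character(0), resnoL = integer(0),
             icodeL = character(0), resnameL = character(0),
             minDist = numeric(0), classR = character(0),
             classL = character(0), stringsAsFactors = FALSE)
}

#' Polar/non-polar contact columns, both conventions
#'
#' Affinity reports usually print only "Polar: Polar" and
#' "Non-Polar: Non-Polar" contact columns without stating whether charged
#' residues were folded into "polar". Both readings are returned: `strict`
#' keeps charged separate (`pp`, `aa`), `folded` merges charged into polar
#' (`pp + cp + cc`, `aa`).
#'
#' @param table a [ContactTable-class].
#' @return named list with `strict` and `folded` two-element vectors.
#' @export
polarContactColumns <- function(table) {
  ct <- contactCounts(table)
  list(strict = c(polar_polar = unname(ct["pp"]),
                  nonpolar_nonpolar = unname(ct["aa"])),
       folded = c(polar_polar = unname(ct["pp"] + ct["cp"] + ct["cc"]),
                  nonpolar_nonpolar = unname(ct["aa"])))
}

#' Contact-based linear affinity model
#'
#' The published linear model that predicts binding affinity from
#' interfacial-contact class counts and the percentage composition of the
#' non-interacting surface (NIS). Weights, intercept and term definitions
#' ship as a versioned config file (`affinity_model.json`) and are loaded,
#' never hard-coded, so the model is replaceable data.
#'
#' @return list with `weights` (named numeric over model terms),
#'   `intercept`, `temperature` (K) and `version`.
#' @export
defaultAffinityModel <- function() {
  cfg <- read_config_json("affinity_model.json")
  list(weights = unlist(cfg$weights), intercept = cfg$intercept,
       temperature = cfg$temperature, version = cfg$version)
}

#' Binding affinity from contacts and NIS percentages
#'
#' `dG = sum(weight_term * term) + intercept` over the model's terms. Terms
#' are looked up by name in the combined vector of contact-class counts
#' (`cc, cp, ca, pp, pa, aa`) and NIS percentages (`nis_apolar`,
#' `nis_charged`); a weight whose term is missing is an error.
#'
#' @param table a [ContactTable-class] (or a named numeric of counts).
#' @param nis named numeric with the NIS percentage terms the model needs
#'   (e.g. `nis_apolar`, `nis_charged`), see [nisPercentages()].
#' @param model an affinity model, see [defaultAffinityModel()].
#' @return dG in kcal/mol.
#' @export
bindingAffinity <- function(table, nis = c(nis_apolar = 0, nis_charged = 0),
                            model = defaultAffinityModel()) {
  counts <- if (is(table, "ContactTable")) contactCounts(table) else table
  terms <- c(counts, nis)
  w <- model$weights
  missing <- setdiff(names(w), names(terms))
  if (length(missing))
    stop("no value for model term(s): ", paste(missing, collapse = ", "))
  sum(w * terms[names(w)]) + model$intercept
}

#' Non-interacting surface composition
#'
#' Percentage of apolar and of charged residues on the complex surface
#' outside the interface. Surface residues are those whose relative SASA in
#' the complex is at least `relCutoff` of the residue's reference maximum
#' area (bundled table, config `max_asa.json`); interface residues
#' (`dSASA > 0`) are removed, and the percentages are taken over what
#' remains.
#'
#' @inheritParams deltaSASA
#' @param scheme residue classification, see [defaultResidueClasses()].
#' @param relCutoff relative-SASA cutoff defining surface residues
#'   (default 0.05).
#' @param profile optional precomputed [deltaSASA()] result; also reused for
#'   the bound residue areas when it carries them.
#' @return named numeric: `nis_apolar`, `nis_charged` (percent).
#' @export
nisPercentages <- function(complexed, receptorChains, ligandChains,
                           scheme = defaultResidueClasses(),
                           radii = defaultRadii(), nPoints = 960,
                           relCutoff = 0.05, profile = NULL) {
  if (is.null(profile))
    profile <- deltaSASA(complexed, receptorChains, ligandChains,
                         radii, nPoints)
  bound <- sasa(complexed, radii, nPoints)$residue
  maxasa <- unlist(read_config_json("max_asa.json")$area)
  ref <- maxasa[bound$resname]
  ref[is.na(ref)] <- mean(maxasa)
  rel <- bound$area / ref
  key <- function(df) paste(df$chain, df$resno, df$icode, sep = "\r")
  iface <- profile$interface[match(key(bound), key(profile))]
  nis_set <- bound[rel >= relCutoff & !iface, , drop = FALSE]
  if (!nrow(nis_set))
    return(c(nis_apolar = 0, nis_charged = 0))
  cls <- scheme[aaThreeToOne(nis_set$resname)]
  c(nis_apolar = 100 * mean(cls == "apolar", na.rm = TRUE),
    nis_charged = 100 * mean(cls == "charged", na.rm = TRUE))
}

#' Dissociation constant from binding affinity, and back
#'
#' `Kd = exp(dG / (R * T))` with `R = 1.9872e-3` kcal/(mol K); the inverse
#' is `dG = R * T * log(Kd)`. Default temperature 298.15 K (25 C).
#'
#' @param dG binding affinity, kcal/mol.
#' @param T temperature, K.
#' @return Kd in M (or dG in kcal/mol for [dgFromKd()]).
#' @examples
#' kdFromDG(0)              # 1
#' dgFromKd(kdFromDG(-8.1)) # -8.1
#' @export
kdFromDG <- function(dG, T = 298.15) {
  if (any(T <= 0)) stop("temperature must be positive")
  exp(dG / (.GAS_CONSTANT_KCAL * T))
}

#' @rdname kdFromDG
#' @param kd dissociation constant, M.
#' @export
dgFromKd <- function(kd, T = 298.15) {
  if (any(T <= 0)) stop("temperature must be positive")
  .GAS_CONSTANT_KCAL * T * log(kd)
}

#' Full interface characterization of a docked complex
#'
#' Runs [deltaSASA()], [interfacialContacts()], [nisPercentages()] and
#' [bindingAffinity()] on one complex and bundles the results with the
#' dissociation constant at the model temperature.
#'
#' @inheritParams interfacialContacts
#' @param model affinity model, see [defaultAffinityModel()].
#' @param nPoints SASA quadrature points.
#' @param radii radius set.
#' @return an [InterfaceReport-class].
#' @export
interfaceReport <- function(complexed, receptorChains, ligandChains,
                            scheme = defaultResidueClasses(),
                            threshold = 5.5, radii = defaultRadii(),
                            nPoints = 960, model = defaultAffinityModel()) {
  profile <- deltaSASA(complexed, receptorChains, ligandChains, radii,
                       nPoints)
  contacts <- interfacialContacts(complexed, receptorChains, ligandChains,
                                  scheme, threshold)
  nis <- nisPercentages(complexed, receptorChains, ligandChains, scheme,
                        radii, nPoints, profile = profile)
  dG <- bindingAffinity(contacts, nis, model)
  Tk <- model$temperature
  new("InterfaceReport", id = complexed@id, deltaSASA = profile,
      contacts = contacts, nis = nis, dG = dG, kd = kdFromDG(dG, Tk),
      temperature = Tk)
}

#' Write an interface report as JSON and TSV
#'
#' JSON carries the per-residue dSASA profile, interface list, contact
#' table, NIS terms, dG and Kd. The TSV mirrors the usual affinity-table
#' layout: complex id, dG, Kd, polar:polar, nonpolar:nonpolar (strict
#' convention; the folded convention is included in the JSON).
#'
#' @param report an [InterfaceReport-class].
#' @param json,tsv optional output paths.
#' @return list with the JSON string and the one-row TSV `data.frame`.
#' @export
writeInterfaceReport <- function(report, json = NULL, tsv = NULL) {
  cols <- polarContactColumns(report@contacts)
  payload <- list(
    id = report@id,
    temperature_K = report@temperature,
    dG_kcal_mol = report@dG,
    Kd_M = report@kd,
    nis_percent = as.list(report@nis),
    contact_counts = as.list(contactCounts(report@contacts)),
    contact_columns = cols,
    interface_residues = report@deltaSASA[report@deltaSASA$interface,
                                          c("chain", "resno", "resname",
                                            "side")],
    delta_sasa = report@deltaSASA)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  row <- data.frame(complex = report@id,
                    dG = round(report@dG, 1),
                    Kd = signif(report@kd, 2),
                    polar_polar = cols$strict["polar_polar"],
                    nonpolar_nonpolar = cols$strict["nonpolar_nonpolar"],
                    row.names = NULL)
  if (!is.null(json)) writeLines(js, json)
  if (!is.null(tsv))
    utils::write.table(row, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(json = js, table = row)
}
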