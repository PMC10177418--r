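#' Packaged indicator-protein reference table
#'
#' Proteins identified in the numbered SDS-PAGE fractions of urine by
#' in-gel tryptic digestion and LC-MS/MS, together with the clinical
#' indicator proteins of the main proteinuria types: albumin and
#' transferrin (glomerular), alpha-1-microglobulin (the AMBP precursor),
#' retinol-binding protein, neutrophil gelatinase-associated lipocalin,
#' cystatin C and beta-2-microglobulin (tubular), and the immunoglobulin
#' free light chain, hemoglobin, myoglobin and lysozyme (overload). The
#' free-light-chain dimer (46 kDa) is carried as a distinct entry from
#' the 23 kDa monomer because non-reduced SDS-PAGE shows both forms.
#' Ovalbumin (44.29 kDa, mature-chain value from UniProt P01012, not from
#' the fraction identifications) is included for the egg-white-adulterant
#' signature.
#'
#' @param path optional CSV to read instead of the packaged table.
#' @return data.frame with columns `protein`, `mw_kda`, `category`
#'   (glomerular_indicator, tubular_indicator, overload_indicator,
#'   other) and `fractions` (';'-separated source fraction numbers).
#' @examples
#' head(referenceProteins())
#' @export
referenceProteins <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "reference_proteins.csv",
                            package = "urinePAGE", mustWork = TRUE)
    d <- utils::read.csv(path, colClasses = c("character", "numeric",
                                              "character", "character"))
    stopifnot(all(d$mw_kda > 0),
              all(d$category %in% c("glomerular_indicator",
                                    "tubular_indicator",
                                    "overload_indicator", "other")))
    d
}

#' Packaged LC-MS/MS fraction identifications
#'
#' Per-fraction protein identifications with peptide-sequence-match (PSM)
#' counts for the 15 Coomassie-visible fractions of a low-molecular-
#' weight-rich urine sample.
#'
#' @return data.frame with columns `fraction`, `protein`, `psm`,
#'   `mw_kda`.
#' @export
lcmsFractions <- function() {
    path <- system.file("extdata", "lcms_fractions.csv",
                        package = "urinePAGE", mustWork = TRUE)
    utils::read.csv(path)
}

#' Annotate bands with reference proteins by molecular weight
#'
#' Each band (with an MW estimate) is matched to every reference protein
#' whose molecular weight lies within `relTol` relative distance of the
#' band's; co-migrating proteins produce multiple matches, which are
#' reported rather than forced unique. Bands with no match within
#' tolerance are flagged unannotated.
#'
#' @param bands data.frame with an `mw_kda` column (and any further band
#'   columns, carried through by row index).
#' @param reference reference table, see [referenceProteins()]; must be
#'   non-empty.
#' @param relTol relative MW tolerance in (0, 0.5]; the distance is
#'   |band MW - reference MW| / band MW.
#' @return data.frame with one row per (band, match): `band` (row index
#'   into `bands`), `band_mw_kda`, `protein`, `ref_mw_kda`, `category`,
#'   `rel_dist`, `unannotated`; unannotated bands contribute a single
#'   row with NA match fields. Matches for a band are sorted by relative
#'   distance.
#' @examples
#' matchBands(data.frame(mw_kda = c(69.0, 13.5)), relTol = 0.1)
#' @export
matchBands <- function(bands, reference = referenceProteins(),
                       relTol = 0.1) {
    stopifnot(is.data.frame(bands), "mw_kda" %in% names(bands))
    if (!is.data.frame(reference) || !nrow(reference))
        stop("reference table must be a non-empty data.frame")
    if (relTol <= 0 || relTol > 0.5) stop("relTol must be in (0, 0.5]")
    out <- lapply(seq_len(nrow(bands)), function(i) {
        mw <- bands$mw_kda[i]
        rel <- abs(reference$mw_kda - mw) / mw
        hit <- which(rel <= relTol)
        if (!length(hit))
            return(data.frame(band = i, band_mw_kda = mw,
                              protein = NA_character_,
                              ref_mw_kda = NA_real_,
                              category = NA_character_,
                              rel_dist = NA_real_, unannotated = TRUE))
        hit <- hit[order(rel[hit])]
        data.frame(band = i, band_mw_kda = mw,
                   protein = reference$protein[hit],
                   ref_mw_kda = reference$mw_kda[hit],
                   category = reference$category[hit],
                   rel_dist = rel[hit], unannotated = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Shortlist LC-MS/MS candidates for a gel fraction
#'
#' Reduces a fraction's full identification list to the abundant
#' proteins: keep candidates whose molecular weight is within
#' `mwRelTol` relative distance of the fraction's apparent MW and whose
#' PSM count reaches `minPsm`, sorted by PSM descending (ties keep their
#' input order).
#'
#' @param candidates data.frame with columns `protein`, `mw_kda`, `psm`.
#' @param fractionMw apparent molecular weight of the fraction, kDa
#'   (> 0).
#' @param mwRelTol relative MW tolerance; the distance is
#'   |candidate MW - fraction MW| / fraction MW.
#' @param minPsm minimum PSM count.
#' @return the filtered, sorted subset of `candidates` (possibly empty).
#' @examples
#' cand <- subset(lcmsFractions(), fraction == 15)
#' shortlistFractionProteins(cand, fractionMw = 14)
#' @export
shortlistFractionProteins <- function(candidates, fractionMw,
                                      mwRelTol = 0.25, minPsm = 10L) {
    stopifnot(is.data.frame(candidates),
              all(c("protein", "mw_kda", "psm") %in% names(candidates)))
    if (fractionMw <= 0) stop("fractionMw must be positive")
    if (nrow(candidates) &&
        (any(candidates$psm < 1) || any(candidates$mw_kda <= 0)))
        stop("candidates need psm >= 1 and positive mw_kda")
    keep <- abs(candidates$mw_kda - fractionMw) / fractionMw <= mwRelTol &
        candidates$psm >= minPsm
    out <- candidates[keep, , drop = FALSE]
    out <- out[order(-out$psm), , drop = FALSE]  # stable for ties
    rownames(out) <- NULL
    out
}
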