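# Accurate-mass peak annotation with knowledge-based candidate filtering:
# 10 ppm matching against a reference table, then (a) adduct-class
# consistency, (b) isotope-pattern plausibility, (c) chain-length
# plausibility, (d) even-chain preference on ties.

#' Default adduct-class consistency rules
#'
#' Choline-bearing (and otherwise readily protonated) classes are expected as
#' positive-mode adducts; acidic classes as deprotonated or chloride adducts
#' in negative mode. The table is configurable because adduct formation
#' varies between lipids and matrices.
#'
#' @return data frame with columns \code{class}, \code{mode}.
#' @export
default_adduct_rules <- function() {
  data.frame(
    class = c("PC", "LPC", "SM", "CAR", "WE",
              "FA", "PA", "PG", "PI", "PS", "LPA", "ST", "HexCer",
              "CDP-DG", "PE-Cer", "PE", "FMC"),
    mode = c(rep("pos", 5), rep("neg", 12)),
    stringsAsFactors = FALSE)
}

# coarse structural category per class, used for chain-length windows
chain_category <- function(class) {
  if (class %in% c("FA", "CAR", "LPA", "LPC")) "lyso"
  else if (class %in% c("SM", "PE-Cer", "ST", "HexCer", "FMC")) "sphingoid"
  else "diacyl"
}

#' Default total-carbon plausibility windows
#'
#' @return named list of \code{c(min, max)} total carbons for diacyl,
#'   lyso/free fatty acyl, and sphingoid-containing classes.
#' @export
default_chain_windows <- function() {
  list(diacyl = c(26, 48), lyso = c(12, 26), sphingoid = c(30, 48))
}

#' Predicted (M+1)/M isotope intensity ratio
#'
#' First-order expansion of the 13C / 15N binomial isotope envelope:
#' 0.0107 nC + 0.0037 nN.
#'
#' @param f a \code{lipid_formula} or formula string.
#' @return expected (M+1)/M ratio.
#' @export
isotope_ratio_m1 <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  0.0107 * f[["C"]] + 0.0037 * f[["N"]]
}

#' Match peaks against a reference m/z table
#'
#' Returns every database entry of the same ionization mode whose theoretical
#' m/z lies within \code{tol_ppm} of the peak:
#' \eqn{|10^6 (peak - theo)/theo| \le tol\_ppm}. The database is searched by
#' binary search on its (sorted) m/z column; all qualifying candidates are
#' returned, one row each.
#'
#' @param peaks numeric vector of observed m/z.
#' @param db data frame with columns \code{name}, \code{adduct}, \code{mz},
#'   \code{mode}.
#' @param tol_ppm matching tolerance in ppm.
#' @param mode restrict to one ionization mode (default: all modes in db;
#'   peaks are then matched within every mode present).
#' @return data frame of candidates: \code{peak_mz}, \code{name},
#'   \code{adduct}, \code{theo_mz}, \code{ppm_error}, \code{mode}.
#' @export
match_peaks <- function(peaks, db, tol_ppm = 10, mode = NULL) {
  if (!is.null(mode)) db <- db[db$mode %in% mode, , drop = FALSE]
  out <- list()
  for (m in unique(db$mode)) {
    dm <- db[db$mode == m, , drop = FALSE]
    dm <- dm[order(dm$mz), , drop = FALSE]
    for (p in peaks) {
      lo <- p / (1 + tol_ppm * 1e-6)
      hi <- p / (1 - tol_ppm * 1e-6)
      i1 <- findInterval(lo, dm$mz, left.open = TRUE) + 1
      i2 <- findInterval(hi, dm$mz)
      if (i2 >= i1) {
        idx <- i1:i2
        ppm <- 1e6 * (p - dm$mz[idx]) / dm$mz[idx]
        keep <- abs(ppm) <= tol_ppm
        if (any(keep))
          out[[length(out) + 1]] <- data.frame(
            peak_mz = p, name = dm$name[idx][keep],
            adduct = dm$adduct[idx][keep], theo_mz = dm$mz[idx][keep],
            ppm_error = ppm[keep], mode = m, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(peak_mz = numeric(0), name = character(0),
                      adduct = character(0), theo_mz = numeric(0),
                      ppm_error = numeric(0), mode = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Knowledge-based filtering of annotation candidates
#'
#' Applies, in order: (a) adduct-class consistency (the candidate's class
#' must be plausible for the observed ionization mode); (b) when an isotope
#' envelope is supplied, the observed (M+1)/M ratio must lie within
#' \code{iso_tol} (relative) of the prediction \code{0.0107 nC + 0.0037 nN};
#' (c) class-specific total-carbon windows; (d) among survivors of one peak,
#' candidates with identical molecular formulas (e.g. O-/P- ether isomers)
#' are merged into one ambiguous "A|B" annotation, then even total carbon
#' counts are preferred, then the smallest |ppm error|. A lone odd-chain
#' candidate is retained with \code{parity_preferred = FALSE}. Every
#' rejection is recorded with the rule that fired.
#'
#' @param cands candidate table from \code{\link{match_peaks}}.
#' @param envelopes optional data frame \code{peak_mz}, \code{ratio_m1}
#'   with observed (M+1)/M intensity ratios.
#' @param adduct_rules class-mode consistency table
#'   (\code{\link{default_adduct_rules}}).
#' @param chain_windows carbon windows (\code{\link{default_chain_windows}}).
#' @param iso_tol relative tolerance on the isotope ratio (MALDI intensity
#'   ratios are noisy; default 0.30).
#' @return data frame of annotations (one row per annotated peak):
#'   \code{peak_mz}, \code{annotation}, \code{class}, \code{carbons},
#'   \code{double_bonds}, \code{adduct}, \code{theo_mz}, \code{ppm_error},
#'   flags \code{isotope_ok}, \code{adduct_ok}, \code{chain_ok},
#'   \code{parity_preferred}; rejected candidates with their failed rule in
#'   \code{attr(, "rejections")}.
#' @export
filter_candidates <- function(cands, envelopes = NULL,
                              adduct_rules = default_adduct_rules(),
                              chain_windows = default_chain_windows(),
                              iso_tol = 0.30) {
  if (!nrow(cands)) {
    out <- data.frame(peak_mz = numeric(0), annotation = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "rejections") <- data.frame(peak_mz = numeric(0),
                                          name = character(0),
                                          rule = character(0))
    return(out)
  }
  parsed <- lapply(cands$name, parse_lipid_name)
  cands$class <- vapply(parsed, `[[`, character(1), "class")
  cands$carbons <- vapply(parsed, `[[`, integer(1), "carbons")
  cands$double_bonds <- vapply(parsed, `[[`, integer(1), "double_bonds")
  cands$formula_str <- vapply(parsed, function(p)
    format_formula(lipid_formula(p)), character(1))

  rejections <- data.frame(peak_mz = numeric(0), name = character(0),
                           rule = character(0), stringsAsFactors = FALSE)
  reject <- function(rows, rule) {
    if (!nrow(rows)) return(invisible())
    rejections <<- rbind(rejections,
                         data.frame(peak_mz = rows$peak_mz,
                                    name = rows$name, rule = rule,
                                    stringsAsFactors = FALSE))
  }

  # (a) adduct-class consistency
  ok_mode <- mapply(function(cl, md) {
    allowed <- adduct_rules$mode[adduct_rules$class == cl]
    !length(allowed) || md %in% allowed
  }, cands$class, cands$mode)
  reject(cands[!ok_mode, , drop = FALSE], "adduct_class_consistency")
  cands <- cands[ok_mode, , drop = FALSE]
  cands$adduct_ok <- rep(TRUE, nrow(cands))

  # (b) isotope plausibility (only when an envelope is available)
  cands$isotope_ok <- rep(TRUE, nrow(cands))
  if (!is.null(envelopes) && nrow(cands)) {
    obs <- envelopes$ratio_m1[match(cands$peak_mz, envelopes$peak_mz)]
    pred <- vapply(cands$formula_str, function(fs)
      isotope_ratio_m1(fs), numeric(1))
    bad <- !is.na(obs) & abs(obs - pred) > iso_tol * pred
    reject(cands[bad, , drop = FALSE], "isotope_pattern")
    cands$isotope_ok <- !bad
    cands <- cands[!bad, , drop = FALSE]
  }

  # (c) chain plausibility
  if (nrow(cands)) {
    win <- t(vapply(cands$class, function(cl)
      chain_windows[[chain_category(cl)]], numeric(2)))
    bad <- cands$carbons < win[, 1] | cands$carbons > win[, 2]
    reject(cands[bad, , drop = FALSE], "chain_length")
    cands <- cands[!bad, , drop = FALSE]
  }
  cands$chain_ok <- rep(TRUE, nrow(cands))

  if (!nrow(cands)) {
    out <- data.frame(peak_mz = numeric(0), annotation = character(0),
                      class = character(0), carbons = integer(0),
                      double_bonds = integer(0), adduct = character(0),
                      theo_mz = numeric(0), ppm_error = numeric(0),
                      mode = character(0), isotope_ok = logical(0),
                      adduct_ok = logical(0), chain_ok = logical(0),
                      parity_preferred = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "rejections") <- rejections
    return(out)
  }

  # (d) resolve multiple survivors per peak
  out <- list()
  for (p in unique(cands$peak_mz)) {
    g <- cands[cands$peak_mz == p, , drop = FALSE]
    # merge isomeric alternatives (identical formula) into "A|B"
    merged <- lapply(unique(g$formula_str), function(fs) {
      sub <- g[g$formula_str == fs, , drop = FALSE]
      # stable, readable order: O- before P-, then by name
      eth <- vapply(sub$name, function(n)
        parse_lipid_name(n)$ether %||% NA_character_, character(1))
      sub <- sub[order(match(eth, c("O", "P"), nomatch = 3), sub$name), ,
                 drop = FALSE]
      row <- sub[1, , drop = FALSE]
      row$annotation <- paste(sub$name, collapse = "|")
      row
    })
    merged <- do.call(rbind, merged)
    if (nrow(merged) > 1) {
      even <- merged$carbons %% 2 == 0
      if (any(even)) {
        reject(merged[!even, , drop = FALSE], "odd_chain_disfavored")
        merged <- merged[even, , drop = FALSE]
      }
      o <- order(abs(merged$ppm_error))
      reject(merged[o[-1], , drop = FALSE], "larger_ppm_error")
      merged <- merged[o[1], , drop = FALSE]
    }
    merged$parity_preferred <- merged$carbons %% 2 == 0
    out[[length(out) + 1]] <- merged
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[, c("peak_mz", "annotation", "class", "carbons",
                 "double_bonds", "adduct", "theo_mz", "ppm_error", "mode",
                 "isotope_ok", "adduct_ok", "chain_ok", "parity_preferred")]
  attr(out, "rejections") <- rejections
  out
}

#' Annotate peaks: match then filter
#'
#' Convenience wrapper: \code{\link{match_peaks}} followed by
#' \code{\link{filter_candidates}}.
#'
#' @inheritParams match_peaks
#' @inheritParams filter_candidates
#' @return the filtered annotation table.
#' @export
annotate_peaks <- function(peaks, db, tol_ppm = 10, mode = NULL,
                           envelopes = NULL,
                           adduct_rules = default_adduct_rules(),
                           chain_windows = default_chain_windows(),
                           iso_tol = 0.30) {
  filter_candidates(match_peaks(peaks, db, tol_ppm, mode),
                    envelopes = envelopes, adduct_rules = adduct_rules,
                    chain_windows = chain_windows, iso_tol = iso_tol)
}

#' The bundled lipid reference table
#'
#' A miniature reference of brain and milk polar-lipid species (name,
#' formula, neutral monoisotopic mass, default adduct, mode, adduct m/z)
#' used for chemistry validation and as a small annotation database.
#'
#' @return data frame.
#' @export
lipid_reference <- function() {
  path <- system.file("extdata", "lipid_reference.tsv", package = "lipidmsi")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
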