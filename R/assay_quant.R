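# Plaque-assay quantification: serial-dilution titring with the
# lysis-from-without upper bound, efficiency of plaquing (EOP), editing
# penetrance, and MOI arithmetic.

#' Build a spot series from a serial-dilution plaque assay
#'
#' @param strain_id Strain identifier.
#' @param dilution_exponents Integer vector: the i-th spot was plated at
#'   dilution factor `10^-exponent` (0 = undiluted).
#' @param counts Per-spot plaque counts; besides numbers the markers
#'   `"TNTC"` (too numerous to count), `"CLEARING"` (clearing without
#'   individual plaques, i.e. lysis from without) and `"NONE"` (no plaques,
#'   no clearing) are accepted.
#' @param spot_volume_ul Spotted volume in microlitres (default 2).
#' @param dilution_base Fold-dilution per step (default 10).
#' @return An object of class `spot_series`.
#' @export
spot_series <- function(strain_id, dilution_exponents, counts,
                        spot_volume_ul = 2, dilution_base = 10) {
  stopifnot(length(dilution_exponents) == length(counts),
            spot_volume_ul > 0, dilution_base > 1)
  if (is.unsorted(dilution_exponents, strictly = TRUE)) {
    stop("dilution exponents must strictly increase (most concentrated first)",
         call. = FALSE)
  }
  counts <- as.character(counts)
  ok <- grepl("^[0-9]+$", counts) | counts %in% c("TNTC", "CLEARING", "NONE")
  if (!all(ok)) {
    stop("invalid count value(s): ", paste(counts[!ok], collapse = ", "),
         call. = FALSE)
  }
  structure(list(strain_id = strain_id,
                 dilution_exponents = as.integer(dilution_exponents),
                 counts = counts,
                 spot_volume_ul = spot_volume_ul,
                 dilution_base = dilution_base),
            class = "spot_series")
}

#' Titre from a spot series
#'
#' Uses the least-diluted spot whose count is countable (inside
#' `count_range`): `pfu/ml = count / (spot volume in ml x dilution factor)`.
#' If no spot is countable but clearing was observed (lysis from without),
#' the most concentrated dilution without individual plaques is approximated
#' as 1 p.f.u. and reported as an upper bound. All spots `NONE` gives titre
#' 0 with a below-detection flag; all spots `TNTC` is an error (the series
#' needs further dilution).
#'
#' @param series A `spot_series`.
#' @param count_range Countable plaque window per spot, default `c(1, 50)`.
#' @return List of class `titre_estimate`: `pfu_per_ml`, `is_upper_bound`,
#'   `below_detection`, `source_exponent`.
#' @export
titre_from_spots <- function(series, count_range = c(1, 50)) {
  stopifnot(inherits(series, "spot_series"))
  vol_ml <- series$spot_volume_ul / 1000
  num <- suppressWarnings(as.numeric(series$counts))
  countable <- !is.na(num) & num >= count_range[1] & num <= count_range[2]
  if (any(countable)) {
    i <- which(countable)[1]                 # least-diluted countable spot
    dil <- series$dilution_base^(-series$dilution_exponents[i])
    return(structure(list(pfu_per_ml = num[i] / (vol_ml * dil),
                          is_upper_bound = FALSE, below_detection = FALSE,
                          source_exponent = series$dilution_exponents[i]),
                     class = "titre_estimate"))
  }
  no_plaque <- series$counts %in% c("CLEARING", "NONE") |
    (!is.na(num) & num == 0)
  if (any(series$counts == "CLEARING")) {
    i <- which(no_plaque)[1]                 # most concentrated plaque-free
    dil <- series$dilution_base^(-series$dilution_exponents[i])
    return(structure(list(pfu_per_ml = 1 / (vol_ml * dil),
                          is_upper_bound = TRUE, below_detection = FALSE,
                          source_exponent = series$dilution_exponents[i]),
                     class = "titre_estimate"))
  }
  if (all(series$counts == "TNTC")) {
    stop("all spots too numerous to count; increase dilution", call. = FALSE)
  }
  structure(list(pfu_per_ml = 0, is_upper_bound = FALSE,
                 below_detection = TRUE, source_exponent = NA_integer_),
            class = "titre_estimate")
}

#' @export
print.titre_estimate <- function(x, ...) {
  cat(sprintf("<titre> %s%.3g p.f.u./ml%s\n",
              if (x$is_upper_bound) "<= " else "", x$pfu_per_ml,
              if (x$below_detection) " (below detection)" else ""))
  invisible(x)
}

#' Efficiency of plaquing
#'
#' `EOP = mean(p.f.u. condition) / mean(p.f.u. non-targeting control)`,
#' with replicate titres averaged before the ratio. The reciprocal is
#' reported as the fold-restriction.
#'
#' @param condition,control Numeric vectors of replicate titres
#'   (p.f.u./ml), or lists of `titre_estimate` objects.
#' @return List of class `eop_result`: `eop`, `fold_restriction`,
#'   `mean_condition`, `mean_control`, `replicates`, `below_detection`.
#' @export
eop <- function(condition, control) {
  condition <- titres_as_numeric(condition)
  control <- titres_as_numeric(control)
  stopifnot(length(condition) >= 1, length(control) >= 1)
  mc <- mean(condition); mn <- mean(control)
  if (mn <= 0) stop("control mean titre is zero; EOP undefined", call. = FALSE)
  e <- mc / mn
  structure(list(eop = e,
                 fold_restriction = if (e > 0) 1 / e else Inf,
                 mean_condition = mc, mean_control = mn,
                 replicates = c(condition = length(condition),
                                control = length(control)),
                 below_detection = mc == 0),
            class = "eop_result")
}

titres_as_numeric <- function(x) {
  if (inherits(x, "titre_estimate")) x <- list(x)
  if (is.list(x)) {
    vapply(x, function(t) if (inherits(t, "titre_estimate")) t$pfu_per_ml
           else as.numeric(t), numeric(1))
  } else as.numeric(x)
}

#' @export
print.eop_result <- function(x, ...) {
  cat(sprintf("<EOP> %.3g (fold-restriction %.3g)%s\n", x$eop,
              x$fold_restriction,
              if (x$below_detection) " [below detection]" else ""))
  invisible(x)
}

#' Editing penetrance
#'
#' `penetrance = p.f.u. on the enrichment (counterselection) strain /
#' p.f.u. on the non-targeting strain`, computed per editing replicate and
#' averaged across replicates (mean +/- s.d.). Values near 1 indicate that
#' essentially the whole population carries the edit. Replicates with a
#' zero denominator are excluded with a warning.
#'
#' @param pfu_enrichment,pfu_negative Numeric vectors, one value per
#'   independent editing attempt.
#' @return List of class `penetrance_result`: `per_replicate`, `mean`,
#'   `sd`, `n`.
#' @export
penetrance <- function(pfu_enrichment, pfu_negative) {
  pfu_enrichment <- titres_as_numeric(pfu_enrichment)
  pfu_negative <- titres_as_numeric(pfu_negative)
  stopifnot(length(pfu_enrichment) == length(pfu_negative))
  bad <- pfu_negative <= 0
  if (any(bad)) {
    warning(sum(bad), " replicate(s) with zero negative-control titre ",
            "excluded", call. = FALSE)
  }
  r <- pfu_enrichment[!bad] / pfu_negative[!bad]
  if (!length(r)) stop("no usable replicates", call. = FALSE)
  structure(list(per_replicate = r, mean = mean(r),
                 sd = if (length(r) > 1) stats::sd(r) else NA_real_,
                 n = length(r)),
            class = "penetrance_result")
}

#' @export
print.penetrance_result <- function(x, ...) {
  cat(sprintf("<penetrance> %.3g +/- %s (n = %d)\n", x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.3g", x$sd), x$n))
  invisible(x)
}

#' Phage particles needed for a target MOI
#'
#' @param cfu Cell count in the well.
#' @param moi Target multiplicity of infection (p.f.u. per c.f.u.).
#' @return p.f.u. to add (`cfu * moi`).
#' @export
#' @examples
#' pfu_for_moi(8e6, 0.01)  # 8e4
pfu_for_moi <- function(cfu, moi) {
  stopifnot(cfu > 0, moi >= 0)
  cfu * moi
}

#' MOI of each step of a serial phage dilution
#'
#' `MOI_i = stock_titre x base^-i x added_volume / cfu` for
#' `i = 0 .. n_dilutions`.
#'
#' @param stock_titre Maximal stock titre in p.f.u./ml.
#' @param added_volume_ml Volume of phage added per well, in ml.
#' @param n_dilutions Number of serial dilution steps.
#' @param cfu Cell count per well.
#' @param base Fold-dilution per step (default 10).
#' @return Numeric vector of MOIs, most concentrated first.
#' @export
#' @examples
#' moi_series(1e11, 0.001, 7, 8e6)  # 12.5 down to 1.25e-6
moi_series <- function(stock_titre, added_volume_ml, n_dilutions, cfu,
                       base = 10) {
  stopifnot(stock_titre >= 0, added_volume_ml >= 0, n_dilutions >= 0,
            cfu > 0)
  i <- 0:n_dilutions
  stock_titre * base^(-i) * added_volume_ml / cfu
}

#' Read a plaque-count table
#'
#' TSV/CSV with columns `strain`, `role` (enrichment / verification /
#' positive / negative / condition / control), `replicate`, `dilution`
#' (exponent) and `count` (number or TNTC / CLEARING / NONE); optional
#' `spot_volume_ul`.
#'
#' @param path File path (delimiter inferred from extension).
#' @return List of `spot_series`, one per strain x replicate, with the
#'   strain roles attached as attribute `roles`.
#' @export
read_plaque_table <- function(path) {
  tb <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "role", "replicate", "dilution", "count")
  if (!all(need %in% names(tb))) {
    stop("plaque table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(tb$strain, tb$replicate, drop = TRUE)
  out <- lapply(split(tb, key), function(d) {
    d <- d[order(d$dilution), ]
    spot_series(d$strain[1], d$dilution, d$count,
                spot_volume_ul = d$spot_volume_ul[1] %||% 2)
  })
  roles <- tapply(tb$role, tb$strain, function(r) r[1])
  attr(out, "roles") <- roles
  out
}

#' Summarize a plaque dataset: titres, EOP and penetrance
#'
#' Titres every series, averages replicates per strain, then computes EOP
#' of every strain against the `negative`/`control` strain and, when an
#' `enrichment` strain is present, the editing penetrance.
#'
#' @param series List of `spot_series` as from [read_plaque_table()].
#' @param count_range Countable window, see [titre_from_spots()].
#' @return List with `titres` (data frame), `eop` (data frame) and
#'   `penetrance` (or `NULL`).
#' @export
quantify_plaque_dataset <- function(series, count_range = c(1, 50)) {
  roles <- attr(series, "roles")
  tt <- lapply(series, titre_from_spots, count_range = count_range)
  strains <- vapply(series, `[[`, "", "strain_id")
  titres <- data.frame(strain = strains,
                       pfu_per_ml = vapply(tt, `[[`, 0, "pfu_per_ml"),
                       is_upper_bound = vapply(tt, `[[`, TRUE,
                                               "is_upper_bound"),
                       row.names = NULL)
  titres$role <- as.character(roles[titres$strain])
  ctrl <- titres$pfu_per_ml[titres$role %in% c("negative", "control")]
  eops <- NULL
  if (length(ctrl)) {
    eops <- do.call(rbind, lapply(split(titres, titres$strain), function(d) {
      data.frame(strain = d$strain[1], role = d$role[1],
                 eop = eop(d$pfu_per_ml, ctrl)$eop)
    }))
    row.names(eops) <- NULL
  }
  pen <- NULL
  enr <- titres[titres$role == "enrichment", , drop = FALSE]
  neg <- titres[titres$role %in% c("negative", "control"), , drop = FALSE]
  if (nrow(enr) && nrow(neg) && nrow(enr) == nrow(neg)) {
    pen <- penetrance(enr$pfu_per_ml, neg$pfu_per_ml)
  }
  list(titres = titres, eop = eops, penetrance = pen)
}
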