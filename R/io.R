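#' Domain constructors
#'
#' Lightweight S3 records for one hemodialysis treatment and its signals.
#' `rbv_trace()` holds the start-normalized relative blood volume (RBV, % of
#' treatment start); `uf_trace()` the machine-reported cumulative
#' ultrafiltration volume (l), which by convention includes the extra
#' ultrafiltration compensating the dialysate bolus; `infusion_event()` the
#' bolus (volume in l, rate in ml/min); `treatment_record()` bundles them with
#' treatment metadata; `bioimpedance_record()` holds the pre-dialysis body
#' composition.
#'
#' @param treatment_id unique identifier (one per patient x study day).
#' @param t sample times, seconds from treatment start, strictly increasing.
#' @param F_b relative blood volume, percent of treatment-start value.
#' @param machine `"M_1perMin"` (nominal 60 s sampling) or `"M_3perMin"`
#'   (nominal 20 s).
#' @return an object of the corresponding class.
#' @export
rbv_trace <- function(treatment_id, t, F_b, machine = c("M_1perMin", "M_3perMin")) {
  machine <- match.arg(machine)
  t <- as.numeric(t); F_b <- as.numeric(F_b)
  if (length(t) != length(F_b)) stop("t and F_b lengths differ")
  if (any(t < 0)) stop("negative time in RBV trace ", treatment_id)
  if (any(diff(t) <= 0)) {
    stop("time not strictly increasing in RBV trace for treatment ",
         treatment_id, call. = FALSE)
  }
  structure(list(treatment_id = treatment_id, t = t, F_b = F_b,
                 machine = machine),
            class = "rbv_trace")
}

#' @rdname rbv_trace
#' @param V_u cumulative ultrafiltration volume (l), non-decreasing up to noise.
#' @export
uf_trace <- function(treatment_id, t, V_u) {
  t <- as.numeric(t); V_u <- as.numeric(V_u)
  if (length(t) != length(V_u)) stop("t and V_u lengths differ")
  if (any(diff(t) <= 0)) {
    stop("time not strictly increasing in UF trace for treatment ",
         treatment_id, call. = FALSE)
  }
  structure(list(treatment_id = treatment_id, t = t, V_u = V_u),
            class = "uf_trace")
}

#' @rdname rbv_trace
#' @param t_inf infusion start (s from treatment start).
#' @param V_inf bolus volume (l).
#' @param Q_inf infusion rate (ml/min).
#' @export
infusion_event <- function(t_inf, V_inf = 0.240, Q_inf = 200) {
  if (V_inf <= 0) stop("V_inf must be > 0")
  if (Q_inf <= 0) stop("Q_inf must be > 0")
  structure(list(t_inf = t_inf, V_inf = V_inf, Q_inf = Q_inf,
                 duration_s = V_inf * 1000 / Q_inf * 60),
            class = "infusion_event")
}

#' @rdname rbv_trace
#' @param patient_id patient identifier.
#' @param study_day integer study day (1-31 for the reference schedule).
#' @param week_index week of study (1-based).
#' @param weekday_treatment treatment within the week, 1, 2 or 3.
#' @param duration_min treatment duration (min).
#' @param M_pre,M_post,M_target pre-, post-dialysis and target body mass (kg).
#' @param rbv an `rbv_trace`.
#' @param uf a `uf_trace`.
#' @param infusion an `infusion_event`, or `NULL` when no bolus was given.
#' @param bp data frame of blood-pressure readings with columns `phase`
#'   (`"pre"`, `"intra"`, `"post"`), `t_min`, `SBP`, `DBP` (mmHg).
#' @export
treatment_record <- function(patient_id, study_day, week_index,
                             weekday_treatment, duration_min, machine,
                             M_pre, M_post, M_target,
                             rbv, uf, infusion = NULL, bp = NULL) {
  if (!weekday_treatment %in% 1:3) {
    stop("weekday_treatment must be 1, 2 or 3 (patient ", patient_id,
         ", day ", study_day, ")", call. = FALSE)
  }
  if (!is.na(duration_min) && duration_min <= 0) stop("duration must be > 0")
  flags <- character(0)
  if (!is.na(M_pre) && !is.na(M_post) && M_post > M_pre) {
    flags <- c(flags, "mass_gain")  # flagged, not rejected
  }
  structure(list(patient_id = patient_id, study_day = as.integer(study_day),
                 week_index = as.integer(week_index),
                 weekday_treatment = as.integer(weekday_treatment),
                 duration_min = duration_min, machine = machine,
                 M_pre = M_pre, M_post = M_post, M_target = M_target,
                 rbv = rbv, uf = uf, infusion = infusion, bp = bp,
                 flags = flags,
                 treatment_id = paste0(patient_id, "_d",
                                       sprintf("%02d", as.integer(study_day)))),
            class = "treatment_record")
}

#' @rdname rbv_trace
#' @param V_ecf,V_icf,V_tbf,V_isf extracellular / intracellular / total-body /
#'   interstitial fluid volume (l).
#' @param V_fo fluid overload (l).
#' @param F_fo_ecf relative fluid overload, % of extracellular fluid.
#' @param M_eu euvolemic body mass (kg).
#' @param LTI,FTI,BMI lean / fat tissue mass index and body mass index (kg/m2).
#' @export
bioimpedance_record <- function(patient_id, study_day, V_ecf, V_icf, V_tbf,
                                V_isf, V_fo, F_fo_ecf, M_eu, LTI, FTI, BMI) {
  structure(list(patient_id = patient_id, study_day = as.integer(study_day),
                 V_ecf = V_ecf, V_icf = V_icf, V_tbf = V_tbf, V_isf = V_isf,
                 V_fo = V_fo, F_fo_ecf = F_fo_ecf, M_eu = M_eu,
                 LTI = LTI, FTI = FTI, BMI = BMI),
            class = "bioimpedance_record")
}

#' Consistency checks on a bioimpedance record
#'
#' Flags violations of the internal identities of body-composition output:
#' total body fluid must equal extracellular plus intracellular volume,
#' relative fluid overload must equal `100 * V_fo / V_ecf`, and euvolemic mass
#' must equal pre-dialysis mass minus fluid overload (1 l of fluid is taken as
#' 1 kg of mass). Returns character flags, never raises.
#'
#' @param r a [bioimpedance_record()].
#' @param M_pre pre-dialysis body mass (kg) of the matching treatment, or `NA`.
#' @param tol_l,tol_kg,tol_pct tolerances (default 0.1 l, 0.1 kg, 0.5 %).
#' @return character vector of flags among `"tbf_sum"`, `"fo_ratio"`,
#'   `"eu_mass"`; empty when consistent.
#' @export
validate_bioimpedance <- function(r, M_pre = NA, tol_l = 0.1, tol_kg = 0.1,
                                  tol_pct = 0.5) {
  flags <- character(0)
  ok <- function(x) !is.null(x) && length(x) == 1 && !is.na(x)
  if (ok(r$V_tbf) && ok(r$V_ecf) && ok(r$V_icf) &&
      abs(r$V_tbf - (r$V_ecf + r$V_icf)) > tol_l) {
    flags <- c(flags, "tbf_sum")
  }
  if (ok(r$F_fo_ecf) && ok(r$V_fo) && ok(r$V_ecf) &&
      abs(r$F_fo_ecf - 100 * r$V_fo / r$V_ecf) > tol_pct) {
    flags <- c(flags, "fo_ratio")
  }
  if (ok(M_pre) && ok(r$M_eu) && ok(r$V_fo) &&
      abs(r$M_eu - (M_pre - r$V_fo)) > tol_kg) {
    flags <- c(flags, "eu_mass")
  }
  flags
}

fmt_num <- function(x) {
  # fixed 6-decimal formatting: guarantees bitwise-stable CSV round-trips
  ifelse(is.na(x), "", sprintf("%.6f", x))
}

#' Write a treatment bundle to disk
#'
#' Writes the documented CSV dialect: `treatments.csv`, `bioimpedance.csv`,
#' `bp.csv` plus per-treatment `rbv/<id>.csv` and `uf/<id>.csv`. All numbers
#' are written with six decimals so that write-read-write round-trips are
#' byte-identical.
#'
#' @param records list with elements `treatments` (list of
#'   [treatment_record()]) and `bioimpedance` (list of
#'   [bioimpedance_record()]).
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_treatment_bundle <- function(records, path) {
  dir.create(file.path(path, "rbv"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "uf"), recursive = TRUE, showWarnings = FALSE)
  txs <- records$treatments
  meta <- data.frame(
    patient_id = vapply(txs, `[[`, "", "patient_id"),
    study_day = vapply(txs, `[[`, 0L, "study_day"),
    week_index = vapply(txs, `[[`, 0L, "week_index"),
    weekday_treatment = vapply(txs, `[[`, 0L, "weekday_treatment"),
    duration_min = fmt_num(vapply(txs, `[[`, 0, "duration_min")),
    machine = vapply(txs, `[[`, "", "machine"),
    M_pre_kg = fmt_num(vapply(txs, `[[`, 0, "M_pre")),
    M_post_kg = fmt_num(vapply(txs, `[[`, 0, "M_post")),
    M_target_kg = fmt_num(vapply(txs, `[[`, 0, "M_target")),
    t_inf_s = fmt_num(vapply(txs, function(x)
      if (is.null(x$infusion)) NA_real_ else x$infusion$t_inf, 0)),
    V_inf_l = fmt_num(vapply(txs, function(x)
      if (is.null(x$infusion)) NA_real_ else x$infusion$V_inf, 0)),
    Q_inf_ml_min = fmt_num(vapply(txs, function(x)
      if (is.null(x$infusion)) NA_real_ else x$infusion$Q_inf, 0)),
    stringsAsFactors = FALSE
  )
  write.csv(meta, file.path(path, "treatments.csv"), row.names = FALSE,
            quote = FALSE)
  for (tx in txs) {
    write.csv(data.frame(t_s = fmt_num(tx$rbv$t), F_b_pct = fmt_num(tx$rbv$F_b)),
              file.path(path, "rbv", paste0(tx$treatment_id, ".csv")),
              row.names = FALSE, quote = FALSE)
    write.csv(data.frame(t_s = fmt_num(tx$uf$t), V_u_l = fmt_num(tx$uf$V_u)),
              file.path(path, "uf", paste0(tx$treatment_id, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  bios <- records$bioimpedance
  bio <- data.frame(
    patient_id = vapply(bios, `[[`, "", "patient_id"),
    study_day = vapply(bios, `[[`, 0L, "study_day"),
    V_ecf_l = fmt_num(vapply(bios, `[[`, 0, "V_ecf")),
    V_icf_l = fmt_num(vapply(bios, `[[`, 0, "V_icf")),
    V_tbf_l = fmt_num(vapply(bios, `[[`, 0, "V_tbf")),
    V_isf_l = fmt_num(vapply(bios, `[[`, 0, "V_isf")),
    V_fo_l = fmt_num(vapply(bios, `[[`, 0, "V_fo")),
    F_fo_ecf_pct = fmt_num(vapply(bios, `[[`, 0, "F_fo_ecf")),
    M_eu_kg = fmt_num(vapply(bios, `[[`, 0, "M_eu")),
    LTI = fmt_num(vapply(bios, `[[`, 0, "LTI")),
    FTI = fmt_num(vapply(bios, `[[`, 0, "FTI")),
    BMI = fmt_num(vapply(bios, `[[`, 0, "BMI")),
    stringsAsFactors = FALSE
  )
  write.csv(bio, file.path(path, "bioimpedance.csv"), row.names = FALSE,
            quote = FALSE)
  bp_rows <- do.call(rbind, lapply(txs, function(tx) {
    if (is.null(tx$bp) || nrow(tx$bp) == 0) return(NULL)
    data.frame(patient_id = tx$patient_id, study_day = tx$study_day,
               phase = tx$bp$phase, t_min = fmt_num(tx$bp$t_min),
               SBP_mmHg = fmt_num(tx$bp$SBP), DBP_mmHg = fmt_num(tx$bp$DBP),
               stringsAsFactors = FALSE)
  }))
  if (is.null(bp_rows)) {
    bp_rows <- data.frame(patient_id = character(0), study_day = integer(0),
                          phase = character(0), t_min = character(0),
                          SBP_mmHg = character(0), DBP_mmHg = character(0))
  }
  write.csv(bp_rows, file.path(path, "bp.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_num <- function(df, col, file) {
  if (!col %in% names(df)) {
    stop("missing mandatory column '", col, "' in ", file, call. = FALSE)
  }
  as.numeric(df[[col]])
}

#' Read and validate a treatment bundle
#'
#' Loads the CSV bundle written by [write_treatment_bundle()] (or an external
#' dataset in the same dialect), builds validated [treatment_record()] and
#' [bioimpedance_record()] objects, and rejects malformed inputs with located
#' messages (file/column for format errors, treatment id for invariant
#' violations such as non-monotone time).
#'
#' @param path bundle directory.
#' @return list with `treatments` and `bioimpedance` lists.
#' @export
read_treatment_bundle <- function(path) {
  tf <- file.path(path, "treatments.csv")
  if (!file.exists(tf)) stop("missing treatments.csv in ", path, call. = FALSE)
  meta <- read.csv(tf, stringsAsFactors = FALSE)
  for (col in c("patient_id", "study_day", "week_index", "weekday_treatment",
                "duration_min", "machine", "M_pre_kg", "M_post_kg",
                "M_target_kg")) {
    if (!col %in% names(meta)) {
      stop("missing mandatory column '", col, "' in treatments.csv",
           call. = FALSE)
    }
  }
  key <- paste(meta$patient_id, meta$study_day)
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, study_day): ", key[duplicated(key)][1],
         call. = FALSE)
  }
  txs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    row <- meta[i, ]
    id <- paste0(row$patient_id, "_d", sprintf("%02d", as.integer(row$study_day)))
    rfile <- file.path(path, "rbv", paste0(id, ".csv"))
    ufile <- file.path(path, "uf", paste0(id, ".csv"))
    if (!file.exists(rfile)) stop("missing RBV file for ", id, call. = FALSE)
    if (!file.exists(ufile)) stop("missing UF file for ", id, call. = FALSE)
    rdf <- read.csv(rfile, stringsAsFactors = FALSE)
    udf <- read.csv(ufile, stringsAsFactors = FALSE)
    rbv <- rbv_trace(id, read_num(rdf, "t_s", rfile),
                     read_num(rdf, "F_b_pct", rfile), machine = row$machine)
    uf <- uf_trace(id, read_num(udf, "t_s", ufile), read_num(udf, "V_u_l", ufile))
    inf <- NULL
    if ("t_inf_s" %in% names(meta) && !is.na(row$t_inf_s) &&
        nzchar(as.character(row$t_inf_s))) {
      inf <- infusion_event(as.numeric(row$t_inf_s), as.numeric(row$V_inf_l),
                            as.numeric(row$Q_inf_ml_min))
    }
    txs[[i]] <- treatment_record(
      row$patient_id, row$study_day, row$week_index, row$weekday_treatment,
      as.numeric(row$duration_min), row$machine, as.numeric(row$M_pre_kg),
      as.numeric(row$M_post_kg), as.numeric(row$M_target_kg),
      rbv, uf, inf, bp = NULL)
  }
  bpf <- file.path(path, "bp.csv")
  if (file.exists(bpf)) {
    bp <- read.csv(bpf, stringsAsFactors = FALSE)
    if (nrow(bp)) {
      idx <- split(seq_len(nrow(bp)), paste(bp$patient_id, bp$study_day))
      for (i in seq_along(txs)) {
        k <- paste(txs[[i]]$patient_id, txs[[i]]$study_day)
        if (k %in% names(idx)) {
          sub <- bp[idx[[k]], ]
          txs[[i]]$bp <- data.frame(phase = sub$phase,
                                    t_min = as.numeric(sub$t_min),
                                    SBP = as.numeric(sub$SBP_mmHg),
                                    DBP = as.numeric(sub$DBP_mmHg),
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  bios <- list()
  bfile <- file.path(path, "bioimpedance.csv")
  if (file.exists(bfile)) {
    bdf <- read.csv(bfile, stringsAsFactors = FALSE)
    bios <- lapply(seq_len(nrow(bdf)), function(i) {
      b <- bdf[i, ]
      bioimpedance_record(b$patient_id, b$study_day,
                          read_num(bdf, "V_ecf_l", bfile)[i],
                          read_num(bdf, "V_icf_l", bfile)[i],
                          read_num(bdf, "V_tbf_l", bfile)[i],
                          read_num(bdf, "V_isf_l", bfile)[i],
                          read_num(bdf, "V_fo_l", bfile)[i],
                          read_num(bdf, "F_fo_ecf_pct", bfile)[i],
                          read_num(bdf, "M_eu_kg", bfile)[i],
                          read_num(bdf, "LTI", bfile)[i],
                          read_num(bdf, "FTI", bfile)[i],
                          read_num(bdf, "BMI", bfile)[i])
    })
  }
  list(treatments = txs, bioimpedance = bios)
}

#' Assemble the long-format cohort table
#'
#' Melts per-treatment metadata and bioimpedance variables (plus any derived
#' per-treatment summaries) into the long table feeding the statistics layer:
#' one row per (patient, study day, variable). Missing values are kept as
#' explicit `NA` rows so that per-variable observation counts are reportable.
#'
#' @param records as returned by [read_treatment_bundle()].
#' @param summaries optional data frame with columns `patient_id`, `study_day`
#'   and one column per derived variable (e.g. output of [cohort_analyze()]'s
#'   per-treatment summary stage).
#' @return data frame with columns `patient_id`, `study_day`,
#'   `weekday_treatment`, `variable`, `value`; attribute `"n_obs"` holds
#'   per-variable non-missing counts.
#' @export
build_cohort_table <- function(records, summaries = NULL) {
  txs <- records$treatments
  empty <- data.frame(patient_id = character(0), study_day = integer(0),
                      weekday_treatment = integer(0), variable = character(0),
                      value = numeric(0), stringsAsFactors = FALSE)
  if (length(txs) == 0) {
    attr(empty, "n_obs") <- integer(0)
    return(empty)
  }
  key <- vapply(txs, function(x) paste(x$patient_id, x$study_day), "")
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, study_day) in records: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  base <- data.frame(
    patient_id = vapply(txs, `[[`, "", "patient_id"),
    study_day = vapply(txs, `[[`, 0L, "study_day"),
    weekday_treatment = vapply(txs, `[[`, 0L, "weekday_treatment"),
    stringsAsFactors = FALSE
  )
  wide <- cbind(base,
                M_pre = vapply(txs, `[[`, 0, "M_pre"),
                M_post = vapply(txs, `[[`, 0, "M_post"),
                M_target = vapply(txs, `[[`, 0, "M_target"),
                duration = vapply(txs, `[[`, 0, "duration_min"))
  bios <- records$bioimpedance
  if (length(bios)) {
    bkey <- vapply(bios, function(b) paste(b$patient_id, b$study_day), "")
    bi <- match(paste(base$patient_id, base$study_day), bkey)
    for (v in c("V_ecf", "V_icf", "V_tbf", "V_isf", "V_fo", "F_fo_ecf",
                "M_eu", "LTI", "FTI", "BMI")) {
      wide[[v]] <- vapply(bi, function(j)
        if (is.na(j)) NA_real_ else as.numeric(bios[[j]][[v]]), 0)
    }
  }
  if (!is.null(summaries)) {
    si <- match(paste(base$patient_id, base$study_day),
                paste(summaries$patient_id, summaries$study_day))
    for (v in setdiff(names(summaries), c("patient_id", "study_day",
                                          "weekday_treatment"))) {
      wide[[v]] <- vapply(si, function(j)
        if (is.na(j)) NA_real_ else as.numeric(summaries[[v]][j]), 0)
    }
  }
  vars <- setdiff(names(wide), names(base))
  long <- do.call(rbind, lapply(vars, function(v) {
    cbind(base, data.frame(variable = v, value = wide[[v]],
                           stringsAsFactors = FALSE))
  }))
  rownames(long) <- NULL
  attr(long, "n_obs") <- vapply(split(long$value, long$variable),
                                function(x) sum(!is.na(x)), 0L)
  long
}
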