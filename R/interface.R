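# File I/O and the command-line entry point. The long (tidy) measurement
# format is one row per measurement: patient_id, time_months, measure_type
# in {psa, pet}, value; covariates live in a companion table keyed by
# patient_id.

#' Read a long-format patient measurement table
#'
#' Expects a delimited text file with columns `patient_id`, `time_months`,
#' `measure_type` (`"psa"` or `"pet"`) and `value`. PSA rows require
#' `value > 0`; PET rows require `value` in \{0, 1\}. Rows are sorted by
#' time per patient and series (a message flags unsorted input); duplicate
#' (patient, type, time) rows, negative times and invalid values are
#' rejected with a line-numbered error. An optional companion covariate
#' table (one row per patient, `patient_id` plus numeric columns) supplies
#' the covariate vectors; an intercept entry is prepended automatically.
#'
#' @param path measurement CSV path.
#' @param covariate_path optional covariate CSV path.
#' @param cov_mu,cov_gamma,cov_beta character vectors naming the covariate
#'   columns entering each regression (defaults: all columns).
#' @return list of [patient_record()] objects.
#' @export
read_patient_table <- function(path, covariate_path = NULL,
                               cov_mu = NULL, cov_gamma = NULL,
                               cov_beta = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "measure_type", "value")
  if (!all(need %in% names(tab)))
    stop("missing required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$.line <- seq_len(nrow(tab)) + 1L  # header is line 1
  bad <- which(tab$time_months < 0)
  if (length(bad))
    stop("negative time at line ", tab$.line[bad[1]])
  bad <- which(!tab$measure_type %in% c("psa", "pet"))
  if (length(bad))
    stop("unknown measure_type at line ", tab$.line[bad[1]])
  bad <- which(tab$measure_type == "psa" & tab$value <= 0)
  if (length(bad))
    stop("non-positive PSA value at line ", tab$.line[bad[1]])
  bad <- which(tab$measure_type == "pet" & !tab$value %in% c(0, 1))
  if (length(bad))
    stop("non-binary PET value at line ", tab$.line[bad[1]])
  key <- paste(tab$patient_id, tab$measure_type, tab$time_months)
  if (anyDuplicated(key))
    stop("duplicate (patient, type, time) row at line ",
         tab$.line[which(duplicated(key))[1]])
  covs <- NULL
  if (!is.null(covariate_path)) {
    covs <- read.csv(covariate_path, stringsAsFactors = FALSE)
    if (!"patient_id" %in% names(covs))
      stop("covariate table must contain patient_id")
  }
  ids <- unique(tab$patient_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- tab[tab$patient_id == ids[i], , drop = FALSE]
    psa <- sub[sub$measure_type == "psa", , drop = FALSE]
    pet <- sub[sub$measure_type == "pet", , drop = FALSE]
    if (is.unsorted(psa$time_months, strictly = TRUE) ||
        is.unsorted(pet$time_months, strictly = TRUE))
      message("patient ", ids[i], ": input not time-sorted; sorting")
    psa <- psa[order(psa$time_months), , drop = FALSE]
    pet <- pet[order(pet$time_months), , drop = FALSE]
    cv <- list(mu = 1, gamma = 1, beta = 1)
    if (!is.null(covs)) {
      row <- covs[covs$patient_id == ids[i], , drop = FALSE]
      if (nrow(row) != 1)
        stop("covariate table must have exactly one row for patient ",
             ids[i])
      allcols <- setdiff(names(covs), "patient_id")
      pick <- function(sel) {
        cols <- if (is.null(sel)) allcols else sel
        miss <- setdiff(cols, names(row))
        if (length(miss))
          stop("unknown covariate column(s): ", paste(miss, collapse = ", "))
        c(1, as.numeric(row[1, cols]))
      }
      cv <- list(mu = pick(cov_mu), gamma = pick(cov_gamma),
                 beta = pick(cov_beta))
    }
    out[[i]] <- patient_record(
      patient_id = ids[i],
      psa_times = psa$time_months, psa_values = psa$value,
      pet_times = pet$time_months, pet_results = pet$value,
      cov_mu = cv$mu, cov_gamma = cv$gamma, cov_beta = cv$beta)
  }
  out
}

#' Write patient records to the long measurement format
#'
#' Inverse of [read_patient_table()] for the measurement table.
#'
#' @param data list of [patient_record()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(data, path) {
  rows <- lapply(data, function(d) {
    rbind(
      if (length(d$psa_times))
        data.frame(patient_id = d$patient_id, time_months = d$psa_times,
                   measure_type = "psa", value = d$psa_values),
      if (length(d$pet_times))
        data.frame(patient_id = d$patient_id, time_months = d$pet_times,
                   measure_type = "pet", value = d$pet_results))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write covariate vectors of a record list to CSV
#'
#' One row per patient; columns `mu_1..`, `gamma_1..`, `beta_1..`
#' including the leading intercept entries.
#'
#' @param data list of [patient_record()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariate_table <- function(data, path) {
  rows <- lapply(data, function(d) {
    v <- c(list(patient_id = d$patient_id),
           setNames(as.list(d$cov_mu), paste0("mu_", seq_along(d$cov_mu))),
           setNames(as.list(d$cov_gamma),
                    paste0("gamma_", seq_along(d$cov_gamma))),
           setNames(as.list(d$cov_beta),
                    paste0("beta_", seq_along(d$cov_beta))))
    as.data.frame(v)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode raw clinical covariates
#'
#' Applies the standard clinical codings: tumour stage `P_T = 0` for
#' T1/T2 and 1 for T3/T4; nodal involvement `P_N` binary; Gleason split
#' `S = 0` when the score is below 6 or equal to 3+4, 1 otherwise
#' (4+3 and above); resection margins `P_R` binary; four therapy flags
#' (hormone/radio, adjuvant/salvage) and lymphadenectomy pass through as
#' binaries; age optionally standardized over the cohort. Assembles the
#' covariate matrices of the decline-rate, growth-rate and logistic
#' regressions (each with a leading intercept column).
#'
#' @param raw data frame with columns `t_stage` ("T1".."T4"), `n_stage`
#'   (0/1), `gleason` (e.g. "3+3", "3+4", "4+3", "8", "9"), `margins`
#'   (0/1), `ormono_adj`, `ormono_salvage`, `radio_adj`, `radio_salvage`,
#'   `lymphadenectomy` (0/1), `age`.
#' @param standardize_age centre and scale age over the cohort.
#' @return list with the encoded data frame `encoded` and design matrices
#'   `C_mu` (intercept + therapies + lymphadenectomy), `C_gamma`
#'   (intercept + P_R, P_T, P_N, S, age + therapies + lymphadenectomy)
#'   and `C_beta` (intercept + P_R, P_T, P_N, S, age).
#' @export
encode_clinical_covariates <- function(raw, standardize_age = TRUE) {
  need <- c("t_stage", "n_stage", "gleason", "margins", "ormono_adj",
            "ormono_salvage", "radio_adj", "radio_salvage",
            "lymphadenectomy", "age")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (anyNA(raw$age)) {
    who <- which(is.na(raw$age))[1]
    id <- if ("patient_id" %in% names(raw)) raw$patient_id[who] else who
    stop("missing age for patient ", id)
  }
  ok_t <- raw$t_stage %in% c("T1", "T2", "T3", "T4")
  if (!all(ok_t))
    stop("unknown t_stage label: ", raw$t_stage[which(!ok_t)[1]])
  P_T <- as.integer(raw$t_stage %in% c("T3", "T4"))
  g <- as.character(raw$gleason)
  low <- c("2", "3", "4", "5", "6", "2+2", "2+3", "3+2", "3+3", "3+4")
  high <- c("4+3", "7", "8", "9", "10", "4+4", "4+5", "5+4", "5+5")
  ok_g <- g %in% c(low, high)
  if (!all(ok_g)) stop("unknown Gleason label: ", g[which(!ok_g)[1]])
  S <- as.integer(g %in% high)
  age <- raw$age
  if (standardize_age) age <- as.numeric(scale(age))
  enc <- data.frame(P_R = as.integer(raw$margins),
                    P_T = P_T, P_N = as.integer(raw$n_stage), S = S,
                    age = age,
                    ormono_adj = as.integer(raw$ormono_adj),
                    ormono_salvage = as.integer(raw$ormono_salvage),
                    radio_adj = as.integer(raw$radio_adj),
                    radio_salvage = as.integer(raw$radio_salvage),
                    lymphadenectomy = as.integer(raw$lymphadenectomy))
  if ("patient_id" %in% names(raw))
    rownames(enc) <- as.character(raw$patient_id)
  therapy <- c("ormono_adj", "ormono_salvage", "radio_adj",
               "radio_salvage", "lymphadenectomy")
  base <- c("P_R", "P_T", "P_N", "S", "age")
  list(encoded = enc,
       C_mu = as.matrix(cbind(intercept = 1, enc[, therapy])),
       C_gamma = as.matrix(cbind(intercept = 1, enc[, c(base, therapy)])),
       C_beta = as.matrix(cbind(intercept = 1, enc[, base])))
}

#' Serialize posterior draws to a long-format CSV
#'
#' One row per kept draw and scalar parameter, columns `chain`, `draw`,
#' `patient_id` (or `"global"`), `parameter`, `value`. Stable format,
#' inverse of [read_draws()].
#'
#' @param draws a `psa_draws` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  rows <- list()
  pat_fams <- c("lam", "lmu", "lgam", "a", "tau", "sig2")
  for (ch in seq_along(draws$chains)) {
    d <- draws$chains[[ch]]
    B <- nrow(d$lam)
    for (nm in names(d)) {
      m <- d[[nm]]
      for (j in seq_len(ncol(m))) {
        pid <- if (nm %in% pat_fams) draws$ids[j] else "global"
        par <- if (nm %in% pat_fams) nm else
          if (ncol(m) > 1) paste0(nm, "[", j, "]") else nm
        rows[[length(rows) + 1L]] <- data.frame(
          chain = ch, draw = seq_len(B), patient_id = pid,
          parameter = par, value = m[, j])
      }
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a serialized draws table
#'
#' @param path CSV written by [write_draws()].
#' @return data frame with columns `chain`, `draw`, `patient_id`,
#'   `parameter`, `value`.
#' @export
read_draws <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
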