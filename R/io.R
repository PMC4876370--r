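# Plain-text serialization. Numeric columns are written with 17
# significant digits (shortest exact decimal round-trip for doubles), so
# a written panel reloads bit-identically.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a panel to CSV plus a truth sidecar
#'
#' The scores go to a long-format CSV with columns
#' `(individual, time, score)`; the true individual parameters, the
#' condition and the seed go to a JSON sidecar. [read_panel()]
#' reconstructs the panel bit-exactly from the pair.
#'
#' @param panel An `mlar1_panel`.
#' @param csv_path Path of the scores CSV.
#' @param json_path Path of the sidecar; default: `csv_path` with a
#'   `.json` extension.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, csv_path,
                        json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(panel, "mlar1_panel"))
  T <- nrow(panel$scores); N <- ncol(panel$scores)
  long <- data.frame(individual = rep(seq_len(N), each = T),
                     time = rep(seq_len(T), N),
                     score = fmt17(as.vector(panel$scores)))
  utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    condition = unclass(panel$condition),
    seed = panel$seed,
    phi_true = fmt17(panel$phi_true),
    mu_true = fmt17(panel$mu_true))
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a panel written by [write_panel()]
#'
#' @param csv_path Path of the scores CSV.
#' @param json_path Path of the sidecar JSON.
#' @return An `mlar1_panel`, bit-identical to the one written.
#' @export
read_panel <- function(csv_path,
                       json_path = sub("\\.csv$", ".json", csv_path)) {
  long <- utils::read.csv(csv_path, colClasses = c("integer", "integer",
                                                   "character"))
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  N <- max(long$individual); T <- max(long$time)
  scores <- matrix(NA_real_, T, N)
  scores[cbind(long$time, long$individual)] <- as.numeric(long$score)
  cond <- do.call(mlar1_condition, side$condition)
  structure(
    list(scores = scores,
         phi_true = as.numeric(side$phi_true),
         mu_true = as.numeric(side$mu_true),
         condition = cond,
         seed = if (is.null(side$seed) || is.na(side$seed)) NA_integer_
                else as.integer(side$seed)),
    class = "mlar1_panel")
}

#' Write replication records to a flat CSV
#'
#' @param records Replication-record data frame.
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  out <- records
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], fmt17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read replication records written by [write_records()]
#'
#' @param path CSV path.
#' @return Data frame with the original numeric values restored exactly.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path)
  for (col in c("gamma01_hat", "se_gamma01", "sigma_u1_hat",
                "ci_lower", "ci_upper"))
    if (col %in% names(rec)) rec[[col]] <- as.numeric(rec[[col]])
  rec
}

#' Serialize a fit to a JSON record
#'
#' Writes the scalar estimates, interval and diagnostic counts of any of
#' the four fit objects with stable field names.
#'
#' @param fit A fit object.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  keep <- intersect(
    c("gamma01_hat", "se_gamma01", "gamma00_hat", "sigma_u1_hat",
      "sigma_u0_hat", "sigma_e_hat", "ci_gamma01", "phi_individual",
      "n_nonconverged", "n_nonstationary", "converged", "rejected_h0",
      "alpha"),
    names(fit))
  jsonlite::write_json(fit[keep], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write posterior draws to a columnar CSV
#'
#' One row per retained draw: `(parameter, chain, iteration, value)`.
#'
#' @param chains List of per-chain draw matrices (as stored by the
#'   samplers), with column names giving the parameter names.
#' @param path Output path.
#' @param parameter_names Optional parameter names; defaults to the
#'   matrix column names.
#' @export
write_draws <- function(chains, path, parameter_names = NULL) {
  if (is.null(parameter_names))
    parameter_names <- colnames(chains[[1]])
  if (is.null(parameter_names))
    parameter_names <- paste0("par", seq_len(ncol(chains[[1]])))
  rows <- lapply(seq_along(chains), function(ch) {
    m <- chains[[ch]]
    data.frame(parameter = rep(parameter_names, each = nrow(m)),
               chain = ch, iteration = rep(seq_len(nrow(m)),
                                           ncol(m)),
               value = fmt17(as.vector(m)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
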