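# File input/output, the Southern Fulmar fixture, and the consolidated
# analysis report.

#' Read a demographic chain from CSV/TSV or JSON
#'
#' CSV/TSV layout: first row and first column are state labels, body is the
#' transient transition matrix `U` with columns as source states. JSON
#' layout: an object `{"labels": [...], "U": [[row], [row], ...]}`. The
#' matrix is validated with [demographic_chain()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"json"`.
#' @param transpose set `TRUE` if the file stores row-oriented probabilities
#'   (entry (i, j) = probability of moving from i to j).
#' @return A [demographic_chain()].
#' @examples
#' f <- system.file("extdata", "fulmar_ordinary.csv", package = "setoccupancy")
#' read_chain(f)$m
#' @export
read_chain <- function(path, format = c("auto", "csv", "tsv", "json"),
                       transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) soc_stop("ParseError", paste("no such file:", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     json = "json",
                     soc_stop("ParseError",
                              paste("cannot infer format from extension:", ext)))
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$U)) soc_stop("ParseError", "JSON file lacks a 'U' field")
    U <- as.matrix(obj$U)
    labels <- if (!is.null(obj$labels)) as.character(obj$labels) else NULL
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    U <- as.matrix(df)
    if (!is.numeric(U)) soc_stop("ParseError", "matrix body is not numeric")
    labels <- rownames(U)
    if (!identical(rownames(U), colnames(U))) {
      soc_stop("LabelMismatch", "row and column labels differ")
    }
  }
  if (isTRUE(transpose)) U <- t(U)
  demographic_chain(U, labels = labels)
}

#' Write a demographic chain to a labelled CSV file
#'
#' @param chain a [demographic_chain()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "demographic_chain"))
  utils::write.csv(as.data.frame(chain$U), path, row.names = TRUE)
  invisible(path)
}

#' Southern Fulmar worked example (ordinary ice conditions)
#'
#' The four-stage Southern Fulmar life cycle under ordinary sea-ice
#' conditions: pre-breeder, non-breeder, successful breeder, failed breeder.
#' Returns the transient transition matrix together with two named target
#' sets: `Ba` (*adult*: has bred at least once) and `Bb` (*breeding
#' attempt*: currently attempting to breed). Matrices for favourable and
#' unfavourable ice conditions are not shipped; load them from your own
#' files with [read_chain()].
#'
#' @param condition only `"ordinary"` is available.
#' @return List with `chain` (a [demographic_chain()]), `Ba` and `Bb`
#'   (character vectors of state labels).
#' @examples
#' fulmar_fixture()$chain$U
#' @export
fulmar_fixture <- function(condition = "ordinary") {
  if (!identical(condition, "ordinary")) {
    soc_stop("UnknownCondition",
             paste0("only 'ordinary' ships with the package; load ",
                    "favourable/unfavourable matrices from your own files ",
                    "with read_chain()"))
  }
  path <- system.file("extdata", "fulmar_ordinary.csv",
                      package = "setoccupancy")
  chain <- read_chain(path)
  list(chain = chain,
       Ba = chain$labels[2:4],
       Bb = chain$labels[3:4])
}

#' Full set-occupancy analysis report
#'
#' Runs the complete pipeline for one chain and one or more target sets:
#' induced chains, occupancy moments/variance/distribution, reach and return
#' statistics, the requested correlation, and (optionally) seeded Monte-Carlo
#' cross-checks with standard errors. All numbers are stored at full
#' precision; rounding is applied only when printing.
#'
#' @param chain a [demographic_chain()].
#' @param targets a target set, or a named list of target sets.
#' @param k_max highest moment to compute.
#' @param pmf_tol truncation tolerance for distributions.
#' @param correlate_with `"longevity"`, or another target set, or `NULL`.
#' @param simulate number of Monte-Carlo paths per initial state (0 = none).
#' @param seed seed for the simulation (required when `simulate > 0`).
#' @return Object of class `occupancy_report` (print with `round` digits via
#'   `print(x, digits = )`); serialise with [report_to_json()].
#' @examples
#' fx <- fulmar_fixture()
#' rep <- analyze_occupancy(fx$chain, list(breeding = fx$Bb), pmf_tol = 1e-6)
#' rep$sets$breeding$occupancy$mean
#' @export
analyze_occupancy <- function(chain, targets, k_max = 2L, pmf_tol = 1e-9,
                              correlate_with = "longevity",
                              simulate = 0L, seed = NULL) {
  stopifnot(inherits(chain, "demographic_chain"))
  if (!is.list(targets)) targets <- list(target = targets)
  if (is.null(names(targets))) names(targets) <- paste0("set", seq_along(targets))
  if (simulate > 0 && is.null(seed)) {
    soc_stop("ParseError", "simulation requested without a seed")
  }
  lon <- longevity_moments(chain, k_max = k_max)
  sets <- lapply(targets, function(B) {
    an <- set_analysis(chain, B)
    occ <- occupancy_moments(an$sub, an$absorption, k_max = k_max)
    pmf <- occupancy_distribution(an$sub, an$absorption, truncation_tol = pmf_tol)
    reach <- if (an$part$alpha > 0 && !is.null(an$conditional)) {
      reach_statistics(an$conditional, an$absorption, k_max = k_max,
                       truncation_tol = pmf_tol)
    } else NULL
    ret <- if (any(an$sub$defined_r)) {
      return_statistics(an$sub, an$conditional, k_max = k_max,
                        truncation_tol = pmf_tol)
    } else NULL
    corr <- if (identical(correlate_with, "longevity")) {
      correlation_with_longevity(chain, B)
    } else if (!is.null(correlate_with)) {
      covariance_sets(chain, B, correlate_with)
    } else NULL
    emp <- if (simulate > 0) {
      lapply(stats::setNames(chain$labels, chain$labels), function(s0) {
        ps <- simulate_paths(chain, simulate, s0, seed = seed)
        empirical_statistics(ps, B)
      })
    } else NULL
    list(analysis = an, occupancy = occ, occupancy_pmf = pmf,
         reach = reach, return = ret, correlation = corr, empirical = emp)
  })
  structure(list(chain = chain, targets = targets, longevity = lon,
                 sets = sets,
                 options = list(k_max = k_max, pmf_tol = pmf_tol,
                                correlate_with = correlate_with,
                                simulate = simulate, seed = seed)),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, digits = 4, ...) {
  cat("== Set-occupancy analysis ==\n")
  print(x$chain)
  cat("\nLongevity (mean / sd):\n")
  print(round(rbind(mean = x$longevity$mean, sd = x$longevity$sd), digits))
  for (nm in names(x$sets)) {
    s <- x$sets[[nm]]
    cat(sprintf("\n-- Target set '%s': {%s} --\n", nm,
                paste(s$analysis$part$labels_B, collapse = ", ")))
    cat("Occupancy time (mean / sd):\n")
    print(round(rbind(mean = s$occupancy$mean, sd = s$occupancy$sd), digits))
    if (!is.null(s$reach)) {
      cat("Reach probability p_win:\n")
      print(round(s$reach$p_win, digits))
      cat("Reaching time mean (winners):\n")
      print(round(s$reach$time_moments$mean, digits))
    }
    if (!is.null(s$return)) {
      cat("Return probability p_return:\n")
      print(round(s$return$p_return, digits))
      cat("Return time mean (returners):\n")
      print(round(s$return$mean, digits))
    }
    if (!is.null(s$correlation)) {
      cat("Correlation with longevity / second set:\n")
      print(round(s$correlation$corr, digits))
    }
  }
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' Writes the numerical content of the report (inputs echoed, induced-chain
#' matrices, moments, PMFs, passage statistics, correlations) to a JSON
#' string or file. Values are written at full double precision so the report
#' round-trips.
#'
#' @param report an [analyze_occupancy()] result.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "occupancy_report"))
  strip <- function(s) {
    an <- s$analysis
    list(B = an$part$labels_B,
         UK = an$killed$UK, MK = an$killed$MK,
         A = an$absorption$A, pa = an$absorption$pa,
         UC = if (!is.null(an$conditional)) an$conditional$UC,
         MC = if (!is.null(an$conditional)) an$conditional$MC,
         US = an$sub$US, mS = an$sub$mS, pr = an$sub$pr,
         Win = an$sub$Win, Wout = an$sub$Wout,
         occupancy = list(mean = s$occupancy$mean,
                          variance = s$occupancy$variance,
                          moments = s$occupancy$moments),
         occupancy_pmf = list(support = s$occupancy_pmf$support,
                              probs = s$occupancy_pmf$probs,
                              tail_mass = s$occupancy_pmf$tail_mass),
         reach = if (!is.null(s$reach)) list(
           p_win = s$reach$p_win,
           mean = s$reach$time_moments$mean,
           variance = s$reach$time_moments$variance),
         return = if (!is.null(s$return)) list(
           p_return = s$return$p_return,
           mean = s$return$mean, variance = s$return$variance),
         correlation = if (!is.null(s$correlation)) list(
           cov = s$correlation$cov, corr = s$correlation$corr),
         empirical = s$empirical)
  }
  obj <- list(input = list(U = report$chain$U, labels = report$chain$labels,
                           m = report$chain$m),
              options = report$options,
              longevity = list(mean = report$longevity$mean,
                               variance = report$longevity$variance),
              sets = lapply(report$sets, strip))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Export a PMF table as a long-format data frame
#'
#' @param pmf a `pmf_table`.
#' @return `data.frame` with columns `initial_state`, `n`, `probability`.
#' @export
pmf_as_data_frame <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_table"))
  data.frame(initial_state = rep(pmf$labels, times = length(pmf$support)),
             n = rep(pmf$support, each = length(pmf$labels)),
             probability = as.vector(pmf$probs))
}
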