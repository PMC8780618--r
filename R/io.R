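#' Read a head-capsule measurement CSV
#'
#' Expects a header with `width_um` (or `width_mm`, converted to um) and
#' optional `larva_id`, `length_um`/`length_mm`, `collection_day` columns.
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return a [head_capsule_sample()].
#' @export
read_head_capsules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  wcol <- intersect(c("width_um", "width_mm"), names(df))
  if (!length(wcol)) {
    stop("missing required column width_um (or width_mm)", call. = FALSE)
  }
  wcol <- wcol[1]
  w <- suppressWarnings(as.numeric(df[[wcol]]))
  bad <- which(is.na(w) | w <= 0)
  if (length(bad)) {
    stop(sprintf("non-numeric or non-positive width in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (wcol == "width_mm") w <- w * 1000
  lcol <- intersect(c("length_um", "length_mm"), names(df))
  len <- NULL
  if (length(lcol)) {
    lcol <- lcol[1]
    len <- suppressWarnings(as.numeric(df[[lcol]]))
    if (any(!is.na(len) & len <= 0)) {
      stop("non-positive length value", call. = FALSE)
    }
    if (lcol == "length_mm") len <- len * 1000
    if (all(is.na(len))) len <- NULL
  }
  head_capsule_sample(
    w, lengths = len,
    larva_id = if ("larva_id" %in% names(df)) df$larva_id else NULL,
    collection_day = if ("collection_day" %in% names(df)) {
      suppressWarnings(as.numeric(df$collection_day))
    } else NULL
  )
}

#' Read rearing records and their fecundity trajectories
#'
#' `records_path` holds one row per individual with columns
#' `individual_id, sex, treatment, egg_days, l1_days, l2_days, l3_days,
#' pupa_days, died_in_stage, adult_longevity_days` (empty cells allowed);
#' `fecundity_path` is the long-format companion with
#' `individual_id, adult_day, eggs`. Fecundity rows must join to a female
#' record, with at most one row per (individual, day) and no day beyond the
#' female's longevity; a female without fecundity rows gets an all-zero
#' trajectory with a warning.
#'
#' @param records_path individuals CSV.
#' @param fecundity_path daily egg counts CSV.
#' @return list of [individual_record()]s.
#' @export
read_records <- function(records_path, fecundity_path) {
  for (p in c(records_path, fecundity_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  rec <- read.csv(records_path, stringsAsFactors = FALSE)
  fec <- read.csv(fecundity_path, stringsAsFactors = FALSE)
  need_r <- c("individual_id", "sex", "adult_longevity_days")
  if (!all(need_r %in% names(rec))) {
    stop("records CSV must contain columns: ",
         paste(need_r, collapse = ", "), call. = FALSE)
  }
  need_f <- c("individual_id", "adult_day", "eggs")
  if (!all(need_f %in% names(fec))) {
    stop("fecundity CSV must contain columns: ",
         paste(need_f, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(fec$individual_id, rec$individual_id)
  if (length(orphan)) {
    stop("fecundity rows with no matching record: ",
         paste(unique(orphan), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(fec[c("individual_id", "adult_day")])
  if (any(dup)) {
    stop(sprintf("duplicate (individual_id, adult_day) in fecundity row(s): %s",
                 paste(which(dup), collapse = ", ")), call. = FALSE)
  }
  stage_cols <- c(egg = "egg_days", L1 = "l1_days", L2 = "l2_days",
                  L3 = "l3_days", pupa = "pupa_days")
  lapply(seq_len(nrow(rec)), function(i) {
    row <- rec[i, ]
    durs <- NULL
    for (s in names(stage_cols)) {
      col <- stage_cols[[s]]
      if (col %in% names(rec)) {
        v <- suppressWarnings(as.numeric(row[[col]]))
        if (!is.na(v)) durs <- c(durs, setNames(v, s))
      }
    }
    died <- if ("died_in_stage" %in% names(rec) &&
                !is.na(row$died_in_stage) && nzchar(row$died_in_stage)) {
      row$died_in_stage
    } else NULL
    longev <- suppressWarnings(as.numeric(row$adult_longevity_days))
    if (is.na(longev)) longev <- NULL
    frows <- fec[fec$individual_id == row$individual_id, , drop = FALSE]
    eggs <- NULL
    if (nrow(frows)) {
      if (row$sex == "male") {
        stop("fecundity rows given for male individual ",
             row$individual_id, call. = FALSE)
      }
      if (is.null(longev)) {
        stop("fecundity rows for individual without adult longevity: ",
             row$individual_id, call. = FALSE)
      }
      over <- frows$adult_day > ceiling(longev)
      if (any(over)) {
        stop(sprintf("fecundity day %d exceeds longevity %.4g for %s",
                     max(frows$adult_day[over]), longev, row$individual_id),
             call. = FALSE)
      }
      eggs <- rep(0, ceiling(longev))
      eggs[frows$adult_day] <- frows$eggs
    } else if (identical(row$sex, "female") && !is.null(longev)) {
      warning("female ", row$individual_id,
              " has no fecundity rows; assuming zero eggs")
      eggs <- rep(0, ceiling(longev))
    }
    individual_record(
      individual_id = row$individual_id, sex = row$sex,
      stage_durations = durs, died_in_stage = died,
      adult_longevity = longev, daily_eggs = eggs,
      treatment = if ("treatment" %in% names(rec) && !is.na(row$treatment) &&
                      nzchar(row$treatment)) row$treatment else NULL
    )
  })
}

#' Assemble a run report
#'
#' Bundles tool version, the fully resolved configuration, input checksums,
#' per-stage results and collected warnings into a serialisable object.
#'
#' @param tool name of the pipeline stage (`"instar"`, `"lifetable"`,
#'   `"simulate"`).
#' @param config named list of resolved parameters (must include any seed).
#' @param results named list of result objects.
#' @param inputs character vector of input file paths (checksummed).
#' @param warnings character vector of collected warnings.
#' @return object of class `run_report`.
#' @export
run_report <- function(tool, config, results, inputs = character(0),
                       warnings = character(0)) {
  checksums <- if (length(inputs)) {
    setNames(as.character(tools::md5sum(inputs)), basename(inputs))
  } else NULL
  structure(
    list(tool = tool,
         version = as.character(packageVersion("cohortdemog")),
         config = config, input_checksums = checksums,
         results = results, warnings = warnings),
    class = "run_report"
  )
}

json_ready <- function(x) {
  if (inherits(x, "life_table")) return(as.data.frame(unclass(x)))
  if (is.matrix(x)) {
    return(as.data.frame(x))
  }
  if (inherits(x, c("mode_test", "demographic_parameters",
                    "instar_classification", "head_capsule_sample"))) {
    x <- unclass(x)
  }
  if (is.list(x)) return(lapply(x, json_ready))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

#' Write a run report to disk
#'
#' Emits `report.json` (the full report), plus convenience tables:
#' `life_table.csv` and `parameters.json` for demography runs,
#' `instar_classification.csv` for instar runs, and a rounded plain-text
#' `summary.txt`. Numeric JSON content is written at full precision and is
#' byte-identical across reruns with the same inputs and seed (the
#' timestamp lives only in `summary.txt`). Existing files are overwritten;
#' with `backup = TRUE` the previous version is kept as `<name>.bak`.
#'
#' @param report a [run_report()].
#' @param dir output directory (created if needed).
#' @param backup keep `.bak` copies of overwritten files?
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir, backup = FALSE) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (file.access(dir, 2) != 0) stop("unwritable path: ", dir,
                                     call. = FALSE)
  emit <- function(name, writer) {
    path <- file.path(dir, name)
    if (backup && file.exists(path)) {
      file.copy(path, paste0(path, ".bak"), overwrite = TRUE)
    }
    writer(path)
    path
  }
  paths <- c(emit("report.json", function(p) {
    jsonlite::write_json(json_ready(unclass(report)), p, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }))
  res <- report$results
  if (!is.null(res$life_table)) {
    paths <- c(paths, emit("life_table.csv", function(p) {
      write.csv(as.data.frame(unclass(res$life_table))[
        c("x", "lx", "mx", "lxmx")], p, row.names = FALSE)
    }))
  }
  if (!is.null(res$parameters)) {
    paths <- c(paths, emit("parameters.json", function(p) {
      jsonlite::write_json(json_ready(res$parameters), p, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }))
  }
  if (!is.null(res$classification)) {
    paths <- c(paths, emit("instar_classification.csv", function(p) {
      write.csv(res$classification$per_instar, p, row.names = FALSE)
    }))
  }
  paths <- c(paths, emit("summary.txt", function(p) {
    writeLines(render_summary(report), p)
  }))
  invisible(paths)
}

# plain-text summary, rounded like a published life-history table:
# 2 dp for sizes/days, 4 dp for rates
render_summary <- function(report) {
  out <- c(sprintf("cohortdemog %s -- %s run (%s)", report$version,
                   report$tool, format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  res <- report$results
  if (!is.null(res$classification)) {
    cl <- res$classification
    out <- c(out, sprintf("instars: %d%s", cl$n_instars,
                          if (isTRUE(cl$saturated)) " (saturated)" else ""))
    per <- cl$per_instar
    for (i in seq_len(nrow(per))) {
      out <- c(out, sprintf("  instar %d: n=%d, %0.2f +/- %0.2f um (%0.2f-%0.2f)",
                            per$instar[i], per$n[i], per$mean[i], per$se[i],
                            per$min[i], per$max[i]))
    }
    if (length(cl$dyar$ratios)) {
      out <- c(out, sprintf("  Dyar ratios: %s; constant %0.4f",
                            paste(sprintf("%0.4f", cl$dyar$ratios),
                                  collapse = ", "), cl$dyar$constant))
    }
  }
  if (!is.null(res$parameters)) {
    pp <- res$parameters
    est <- pp$estimates
    fmt <- c(R0 = "%0.2f", T = "%0.2f", r_m = "%0.4f", DT = "%0.2f",
             lambda = "%0.4f")
    for (p in names(est)) {
      out <- c(out, sprintf(
        paste0("  %-6s ", fmt[p], " (95%% CI ", fmt[p], "-", fmt[p], ")"),
        p, est[p], pp$ci_95[p, "low"], pp$ci_95[p, "high"]))
    }
  }
  if (length(report$warnings)) {
    out <- c(out, "warnings:", paste(" -", report$warnings))
  }
  out
}

#' Read a JSON analysis configuration
#'
#' Configuration files carry blocks named `morphometrics`, `demography`
#' and/or `synthetic` plus top-level `seed`; unknown top-level keys are
#' rejected so typos fail loudly.
#'
#' @param path JSON file.
#' @return named list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("morphometrics", "demography", "synthetic", "seed",
             "output_dir", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}
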