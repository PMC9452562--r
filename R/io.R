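#' Table schemas used across the pipeline
#'
#' Column names, types and range checks for each input dialect. TSV is the
#' canonical format (tab-separated, UTF-8, '.' decimal, header mandatory);
#' comma-separated files are accepted on ingest.
#'
#' @return Named list of schema definitions.
#' @export
table_schemas <- function() {
  list(
    caliper = list(
      required = c("model_id", "animal_id", "arm", "day", "length_mm", "width_mm"),
      numeric = c("day", "length_mm", "width_mm"),
      checks = list(
        day = function(x) x >= 0,
        length_mm = function(x) is.finite(x) & x > 0,
        width_mm = function(x) is.finite(x) & x > 0
      )
    ),
    panel = list(
      required = c("sample_id", "p16", "prb", "cyclin_e1", "cyclin_d1"),
      numeric = c("p16", "prb", "cyclin_e1", "cyclin_d1"),
      checks = list(
        p16 = function(x) is.na(x) | (x >= 0 & x <= 4),
        prb = function(x) is.na(x) | (x >= 0 & x <= 4),
        cyclin_e1 = function(x) is.na(x) | (x >= 0 & x <= 8),
        cyclin_d1 = function(x) is.na(x) | (x >= 0 & x <= 8)
      )
    ),
    spheroid = list(
      required = c("model_id", "condition", "replicate", "area"),
      numeric = c("area"),
      checks = list(area = function(x) is.finite(x) & x > 0)
    ),
    variant = list(
      required = c("sample_id", "gene"),
      numeric = character(),
      checks = list()
    ),
    copy_number = list(
      required = c("sample_id", "gene"),
      numeric = character(),
      checks = list(
        minor_cn = function(x) is.na(x) | x >= 0,
        major_cn = function(x) is.na(x) | x >= 0
      )
    ),
    cohort = list(
      required = c("patient_id", "exposed", "mutation", "deletion"),
      numeric = c("exposed", "mutation", "deletion"),
      checks = list(
        exposed = function(x) x %in% c(0, 1),
        mutation = function(x) x %in% c(0, 1),
        deletion = function(x) x %in% c(0, 1)
      )
    )
  )
}

#' Validate a delimited table against a pipeline schema
#'
#' Reads a TSV/CSV file (or takes a data frame directly), checks required
#' columns, coercible numeric types and per-column range rules, and returns
#' the validated tibble together with an itemized, line-numbered error
#' report. Line numbers refer to data rows of the file (header = line 1).
#'
#' @param x Path to a TSV/CSV file, or a data frame.
#' @param schema Schema name, one of `names(table_schemas())`.
#' @return A list with `ok` (logical), `data` (tibble, possibly partial) and
#'   `errors` (tibble with `line`, `column`, `message`).
#' @export
validate_table <- function(x, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    stop("unknown schema '", schema, "'; available: ",
      paste(names(schemas), collapse = ", "),
      call. = FALSE
    )
  }
  sch <- schemas[[schema]]
  if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    delim <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    data <- readr::read_delim(x,
      delim = delim, show_col_types = FALSE,
      progress = FALSE
    )
  } else {
    data <- tibble::as_tibble(x)
  }
  errors <- tibble::tibble(
    line = integer(), column = character(), message = character()
  )
  missing <- setdiff(sch$required, names(data))
  if (length(missing)) {
    errors <- dplyr::bind_rows(errors, tibble::tibble(
      line = NA_integer_, column = missing,
      message = paste0("required column '", missing, "' is missing")
    ))
    return(list(ok = FALSE, data = data, errors = errors))
  }
  for (col in intersect(sch$numeric, names(data))) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad)) {
        errors <- dplyr::bind_rows(errors, tibble::tibble(
          line = bad + 1L, column = col,
          message = paste0("non-numeric value '", v[bad], "'")
        ))
      }
      data[[col]] <- coerced
    }
  }
  for (col in names(sch$checks)) {
    if (!col %in% names(data)) next
    ok <- sch$checks[[col]](data[[col]])
    bad <- which(!ok)
    if (length(bad)) {
      errors <- dplyr::bind_rows(errors, tibble::tibble(
        line = bad + 1L, column = col,
        message = paste0("value out of range: ", format(data[[col]][bad]))
      ))
    }
  }
  list(ok = nrow(errors) == 0L, data = data, errors = errors)
}

#' Read a caliper measurement table
#'
#' Reads and validates a TSV/CSV caliper table and normalizes the dimension
#' convention (`width_mm <= length_mm`, swapping on ingest when violated).
#'
#' @param path Path to a TSV or CSV file with columns `model_id`,
#'   `animal_id`, `arm`, `day`, `length_mm`, `width_mm`.
#' @return A validated caliper tibble.
#' @export
read_caliper_table <- function(path) {
  v <- validate_table(path, "caliper")
  if (!v$ok) {
    stop(
      "invalid caliper table:\n",
      paste(utils::capture.output(print(v$errors)), collapse = "\n"),
      call. = FALSE
    )
  }
  v$data %>%
    dplyr::mutate(
      .l = pmax(.data$length_mm, .data$width_mm),
      .w = pmin(.data$length_mm, .data$width_mm),
      length_mm = .data$.l, width_mm = .data$.w
    ) %>%
    dplyr::select(-".l", -".w")
}

#' Recompute the pipeline's desk-checkable worked examples
#'
#' Runs the small worked examples whose inputs are printed numbers: the
#' cohort response rates from the per-class counts of the 21-model screen,
#' the engraftment rate from 58 models established out of 473 implants, the
#' count of derivative tumors of the RB1-shallow-deleted model that carry a
#' deleterious RB1 mutation (from the packaged derivative table), and the
#' copy-number band calls for log-ratios -0.9, -1.5 and -2.0. Each item is
#' recomputed by the package's own functions and compared with the expected
#' value.
#'
#' @return A tibble with `item`, `expected`, `computed`, `pass`; all pass on
#'   an intact installation.
#' @export
reproduce_worked_examples <- function() {
  # pRR/pCB over the 21 evaluable models: 1 CR, 2 PR, 2 SD, 16 PD
  calls <- tibble::tibble(
    mrecist = factor(
      rep(c("CR", "PR", "SD", "PD"), c(1, 2, 2, 16)),
      levels = c("CR", "PR", "SD", "PD")
    )
  )
  cs <- cohort_summary(calls)
  engraft <- engraftment_rate(58, 473)
  variants <- readr::read_tsv(
    system.file("extdata", "pdx244_variants.tsv", package = "cdkresist"),
    show_col_types = FALSE
  )
  cn <- readr::read_tsv(
    system.file("extdata", "pdx244_copynumber.tsv", package = "cdkresist"),
    show_col_types = FALSE
  )
  resistant <- setdiff(unique(cn$sample_id), "2R")
  hits <- call_double_hit(variants, cn,
    gene = "RB1",
    rule_set = "deleterious_truncating"
  )
  n_mut <- sum(hits$mutation_flag[hits$sample_id %in% resistant])
  bands <- as.character(classify_cn_logratio(c(-0.9, -1.5, -2.0)))
  items <- tibble::tibble(
    item = c(
      "pRR_pct", "pCB_pct", "engraftment_pct",
      "rb1_deleterious_of_8", "band_-0.9", "band_-1.5", "band_-2.0"
    ),
    expected = c(
      "14", "24", "12", "3",
      "shallow_del", "deep_del", "deep_del"
    ),
    computed = c(
      as.character(cs$prr_rounded), as.character(cs$pcb_rounded),
      as.character(engraft$rate_pct_rounded), as.character(n_mut),
      bands
    )
  )
  items %>% dplyr::mutate(pass = .data$expected == .data$computed)
}
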