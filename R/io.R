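# Readers and writers binding the pipeline stages together. Delimited
# files are UTF-8, comma-separated on input, tab-separated on output, '.'
# decimal separator, header row mandatory. Metabotypes travel as
# fixed-width mask strings; the marker order behind the bit positions is
# declared in a '# markers:' sidecar header line.

#' Read a genotyping count table
#'
#' CSV with a mandatory first sidecar line declaring the marker order of
#' the mask bits, e.g. `# markers: HIS3,LEU2,URA3,MET15` (tokens may be
#' `id` or `id:metabolite`), followed by a header row and columns
#' `metabotype,count` (an optional leading `colony_id` column is ignored
#' for counting). Duplicate metabotype rows are summed with a warning;
#' masks whose length does not match the declared marker count raise a
#' parse error naming the line.
#'
#' @param path Path to the CSV file.
#' @return List with `counts` (named numeric vector per metabotype mask)
#'   and `markers` (the declared [marker_set()]).
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L)
    stop("genotype table must have a marker header line and a data header")
  hdr <- lines[1]
  if (!grepl("^#\\s*markers\\s*:", hdr))
    stop("first line must declare marker order, e.g. '# markers: HIS3,LEU2'")
  tokens <- trimws(strsplit(sub("^#\\s*markers\\s*:", "", hdr), ",")[[1]])
  ids <- sub(":.*$", "", tokens)
  mets <- ifelse(grepl(":", tokens), sub("^[^:]*:", "", tokens), NA)
  markers <- if (all(is.na(mets))) marker_set(ids)
             else marker_set(ids, ifelse(is.na(mets), tolower(ids), mets))
  k <- n_markers(markers)
  df <- utils::read.csv(text = lines[-1], stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("metabotype", "count") %in% names(df)))
    stop("genotype table needs 'metabotype' and 'count' columns")
  bad <- which(!grepl(sprintf("^[01]{%d}$", k), df$metabotype))
  if (length(bad))
    stop("malformed metabotype mask '", df$metabotype[bad[1]],
         "' (expected ", k, " bits) at line ", bad[1] + 2L, " of ", path)
  cnt <- as.numeric(df$count)
  if (anyNA(cnt) || any(cnt < 0))
    stop("counts must be non-negative numbers")
  if (anyDuplicated(df$metabotype)) {
    warning("duplicate metabotype rows summed in ", path)
    cnt <- tapply(cnt, df$metabotype, sum)
    counts <- stats::setNames(as.numeric(cnt), names(cnt))
  } else {
    counts <- stats::setNames(cnt, df$metabotype)
  }
  list(counts = counts, markers = markers)
}

#' Write a genotyping count table
#'
#' Inverse of [read_genotype_table()].
#'
#' @param counts Named numeric vector of counts per metabotype mask.
#' @param markers The [marker_set()] declaring the bit order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(counts, markers, path) {
  hdr <- paste0("# markers: ",
                paste(paste0(markers$id, ":", markers$metabolite),
                      collapse = ","))
  lines <- c(hdr, "metabotype,count",
             paste(names(counts), counts, sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a segregation scenario configuration from YAML
#'
#' Expected fields: `rates` (map marker id -> per-division loss
#' probability), and optionally `regime`, `supplemented`, `fitness` (map
#' metabotype mask -> weight), `bottleneck` (`interval`, `fraction`),
#' `seed`, `generations`.
#'
#' @param path Path to the YAML file.
#' @param markers A [marker_set()] the rates must cover.
#' @return List with `rates` (named vector), `scenario` (a
#'   [scenario_config()]), and `generations` (or `NULL`).
#' @export
read_scenario_config <- function(path, markers) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rates)) stop("scenario config must declare 'rates'")
  rates <- segregation_rates(unlist(cfg$rates), markers)
  scen <- scenario_config(
    regime = if (is.null(cfg$regime)) "neutral" else cfg$regime,
    supplemented = as.character(unlist(cfg$supplemented)),
    fitness = if (is.null(cfg$fitness)) NULL else unlist(cfg$fitness),
    bottleneck = cfg$bottleneck,
    seed = cfg$seed)
  list(rates = rates, scenario = scen, generations = cfg$generations)
}

#' Write an analysis report
#'
#' Deterministic serialisation of a result list: JSON (key order as given,
#' no timestamps, full numeric precision) or TSV for tabular results
#' (numbers at 6 significant digits). The package version and, when
#' supplied, the seed and configuration are embedded so every report is
#' traceable to its run.
#'
#' @param results A named list (JSON) or data frame (TSV).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @param seed Optional seed to embed.
#' @param config Optional configuration list to embed (JSON only).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "tsv"),
                         seed = NULL, config = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(version = as.character(utils::packageVersion("semeco")))
    if (!is.null(seed)) payload$seed <- seed
    if (!is.null(config)) payload$config <- config
    payload$results <- results
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    if (!is.data.frame(results))
      stop("TSV reports require a data frame")
    df <- results
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    hdr <- c(paste0("# semeco version: ",
                    as.character(utils::packageVersion("semeco"))),
             if (!is.null(seed)) paste0("# seed: ", seed))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a growth-curve CSV
#'
#' Columns `time_hr,value`, or long format with an additional `curve_id`
#' column (one curve per id).
#'
#' @param path Path to the CSV file.
#' @return A [growth_curve()], or a named list of them in long format.
#' @export
read_growth_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_hr", "value") %in% names(df)))
    stop("growth table needs 'time_hr' and 'value' columns")
  if ("curve_id" %in% names(df)) {
    lapply(split(df, df$curve_id),
           function(d) growth_curve(d$time_hr, d$value))
  } else {
    growth_curve(df$time_hr, df$value)
  }
}
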