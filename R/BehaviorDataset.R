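#' Construct a BehaviorDataset
#'
#' @param values numeric matrix or data.frame of behavioral measures, animals
#'   in rows (rownames = animal ids) and measures in columns. \code{NA} marks
#'   a missing cell.
#' @param genotype,sex character vectors, one entry per animal. Sex must be
#'   coded \code{"M"}/\code{"F"}.
#' @param cohort optional per-animal cohort label.
#' @param group optional per-animal treatment-arm label
#'   (e.g. \code{"WT+control"}).
#' @param battery measure battery as returned by [defaultBattery()] or
#'   [readBattery()]: a data.frame with columns \code{name}, \code{units},
#'   \code{impairment_direction}, \code{lo}, \code{hi}, \code{integer_valued}
#'   and optionally \code{test} (the parent behavioral test, used when whole
#'   tests are ablated). If \code{NULL}, a neutral battery (direction +1,
#'   no bounds) is derived from the column names.
#'
#' @return A \linkS4class{BehaviorDataset}.
#' @examples
#' vals <- matrix(rnorm(20), 10, 2,
#'                dimnames = list(paste0("a", 1:10), c("m1", "m2")))
#' ds <- BehaviorDataset(vals, genotype = rep(c("WT", "MUT"), each = 5),
#'                       sex = rep(c("M", "F"), 5))
#' ds
#' @export
BehaviorDataset <- function(values, genotype, sex, cohort = NULL, group = NULL,
                            battery = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("a%03d", seq_len(nrow(values)))
    if (is.null(battery)) {
        battery <- data.frame(name = colnames(values), units = "",
                              impairment_direction = 1, lo = NA_real_,
                              hi = NA_real_, integer_valued = FALSE,
                              test = colnames(values),
                              stringsAsFactors = FALSE)
    }
    battery <- normalizeBattery(battery)
    missing_cols <- setdiff(colnames(values), battery$name)
    if (length(missing_cols))
        stop("measure column(s) not in battery config: ",
             paste(missing_cols, collapse = ", "))
    battery <- battery[match(colnames(values), battery$name), , drop = FALSE]
    n <- nrow(values)
    cd <- DataFrame(genotype = as.character(genotype),
                    sex = as.character(sex),
                    cohort = if (is.null(cohort)) rep(NA_character_, n)
                             else as.character(cohort),
                    group = if (is.null(group)) rep(NA_character_, n)
                            else as.character(group),
                    row.names = rownames(values))
    rd <- DataFrame(battery[, setdiff(colnames(battery), "name"), drop = FALSE],
                    row.names = battery$name)
    se <- SummarizedExperiment(assays = list(measures = t(values)),
                               colData = cd, rowData = rd)
    new("BehaviorDataset", se)
}

# Fill optional battery columns and validate the required ones.
normalizeBattery <- function(battery) {
    battery <- as.data.frame(battery, stringsAsFactors = FALSE)
    if (!"name" %in% colnames(battery)) stop("battery needs a 'name' column")
    if (anyDuplicated(battery$name))
        stop("battery measure names must be unique")
    if (!"units" %in% colnames(battery)) battery$units <- ""
    if (!"impairment_direction" %in% colnames(battery)) battery$impairment_direction <- 1
    if (!"lo" %in% colnames(battery)) battery$lo <- NA_real_
    if (!"hi" %in% colnames(battery)) battery$hi <- NA_real_
    if (!"integer_valued" %in% colnames(battery)) battery$integer_valued <- FALSE
    if (!"test" %in% colnames(battery)) battery$test <- battery$name
    if (!all(battery$impairment_direction %in% c(-1, 1)))
        stop("impairment_direction must be -1 or +1")
    both <- !is.na(battery$lo) & !is.na(battery$hi)
    if (any(both & battery$lo >= battery$hi)) stop("battery bounds need lo < hi")
    canon <- c("name", "test", "units", "impairment_direction", "lo", "hi",
               "integer_valued")
    battery[, c(canon, setdiff(colnames(battery), canon)), drop = FALSE]
}

#' The default eight-measure behavioral battery
#'
#' Weight, rotarod day 1 and day 5, open-field distance and center time,
#' marbles buried, nest building and forced-swim immobility, spanning six
#' behavioral tests. Impairment directions give the expected sign of the
#' mutant-minus-wildtype difference for an impaired animal: heavier (+1),
#' shorter rotarod latency (-1), hypoactive (-1), fewer marbles buried (-1),
#' poorer nest building (-1), more forced-swim immobility (+1).
#'
#' @return data.frame battery usable by [BehaviorDataset()] and
#'   [readBehaviorDataset()].
#' @examples
#' defaultBattery()
#' @export
defaultBattery <- function() {
    data.frame(
        name = c("weight", "rotarod_d1", "rotarod_d5", "of_distance",
                 "of_center_time", "marbles_buried", "nest_building",
                 "forced_swim"),
        test = c("weight", "rotarod", "rotarod", "open_field", "open_field",
                 "marble_burying", "nest_building", "forced_swim"),
        units = c("g", "s", "s", "cm", "s", "count", "pct_material_used",
                  "pct_immobile"),
        impairment_direction = c(1, -1, -1, -1, -1, -1, -1, 1),
        lo = c(NA, 0, 0, 0, 0, 0, 0, 0),
        hi = c(NA, 300, 300, NA, 1800, 20, 100, 100),
        integer_valued = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
        stringsAsFactors = FALSE)
}

#' Read/write a measure battery as JSON
#'
#' The battery JSON is a list of objects with fields \code{name},
#' \code{units}, \code{impairment_direction}, \code{bounds} (two-element
#' array or null), \code{integer_valued} and optional \code{test}.
#'
#' @param path file path.
#' @param battery battery data.frame (see [defaultBattery()]).
#' @return \code{readBattery()} returns the battery data.frame;
#'   \code{writeBattery()} returns \code{path} invisibly.
#' @export
readBattery <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    num1 <- function(v) {
        if (is.null(v) || (length(v) == 1L && is.na(v))) NA_real_ else as.numeric(v)
    }
    rows <- lapply(raw, function(m) {
        b <- m$bounds
        data.frame(name = m$name, units = m$units %||% "",
                   impairment_direction = m$impairment_direction,
                   lo = if (is.null(b)) NA_real_ else num1(b[[1]]),
                   hi = if (is.null(b)) NA_real_ else num1(b[[2]]),
                   integer_valued = isTRUE(m$integer_valued),
                   test = m$test %||% m$name, stringsAsFactors = FALSE)
    })
    normalizeBattery(do.call(rbind, rows))
}

#' @rdname readBattery
#' @export
writeBattery <- function(battery, path) {
    battery <- normalizeBattery(battery)
    out <- lapply(seq_len(nrow(battery)), function(i) {
        b <- battery[i, ]
        list(name = b$name, units = b$units,
             impairment_direction = b$impairment_direction,
             bounds = if (is.na(b$lo) && is.na(b$hi)) NULL
                      else list(if (is.na(b$lo)) NULL else b$lo,
                                if (is.na(b$hi)) NULL else b$hi),
             integer_valued = b$integer_valued, test = b$test)
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}

#' Read a behavioral cohort from CSV
#'
#' Expects a UTF-8, comma-delimited file with header columns
#' \code{animal_id}, \code{genotype}, \code{sex}, optional \code{cohort} and
#' \code{group}, followed by one column per measure. Empty cells and the
#' literal \code{NA} denote missing values; any other non-numeric measure cell
#' is an error (malformed data fail loudly rather than becoming silent
#' missingness). Measure column order is preserved.
#'
#' @param path CSV file path.
#' @param battery battery data.frame or path to a battery JSON; every measure
#'   column in the CSV must be declared here.
#' @return A \linkS4class{BehaviorDataset}.
#' @seealso [writeBehaviorDataset()], [defaultBattery()]
#' @export
readBehaviorDataset <- function(path, battery = defaultBattery()) {
    if (is.character(battery) && length(battery) == 1L) battery <- readBattery(battery)
    battery <- normalizeBattery(battery)
    raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
    need <- c("animal_id", "genotype", "sex")
    miss <- setdiff(need, colnames(raw))
    if (length(miss)) stop("CSV lacks required column(s): ", paste(miss, collapse = ", "))
    meta_cols <- intersect(c("animal_id", "genotype", "sex", "cohort", "group"),
                           colnames(raw))
    measure_cols <- setdiff(colnames(raw), meta_cols)
    bad <- setdiff(measure_cols, battery$name)
    if (length(bad))
        stop("measure column(s) not in battery config: ", paste(bad, collapse = ", "))
    if (anyDuplicated(raw$animal_id))
        stop("duplicate animal_id: ",
             paste(unique(raw$animal_id[duplicated(raw$animal_id)]), collapse = ", "))
    vals <- matrix(NA_real_, nrow(raw), length(measure_cols),
                   dimnames = list(raw$animal_id, measure_cols))
    for (mc in measure_cols) {
        cell <- trimws(raw[[mc]])
        is_missing <- cell == "" | cell == "NA"
        num <- suppressWarnings(as.numeric(cell))
        bad_rows <- which(!is_missing & is.na(num))
        if (length(bad_rows))
            stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                         cell[bad_rows[1]], bad_rows[1], mc))
        num[is_missing] <- NA_real_
        vals[, mc] <- num
    }
    BehaviorDataset(vals, genotype = raw$genotype, sex = raw$sex,
                    cohort = if ("cohort" %in% colnames(raw)) raw$cohort else NULL,
                    group = if ("group" %in% colnames(raw)) raw$group else NULL,
                    battery = battery[battery$name %in% measure_cols, , drop = FALSE])
}

#' Write a behavioral cohort to CSV
#'
#' Writes the same dialect [readBehaviorDataset()] reads, with full numeric
#' precision so that a write/read cycle reproduces the dataset exactly.
#' Missing cells are written as empty strings. The cohort/group columns are
#' included only when any animal carries them.
#'
#' @param ds a \linkS4class{BehaviorDataset}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeBehaviorDataset <- function(ds, path) {
    X <- measureMatrix(ds)
    out <- data.frame(animal_id = animalIds(ds), genotype = genotypes(ds),
                      sex = sexes(ds), stringsAsFactors = FALSE)
    co <- cohorts(ds); gr <- armGroups(ds)
    if (!all(is.na(co))) out$cohort <- co
    if (!all(is.na(gr))) out$group <- gr
    for (m in colnames(X)) out[[m]] <- fmtNum(X[, m])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' Restrict a dataset to animals with complete data on given measures
#'
#' Keeps only animals with a non-missing value for every requested measure and
#' restricts the battery to those measures, preserving the original animal and
#' measure order. Requesting more measures can never increase the number of
#' animals retained, and the operation is idempotent.
#'
#' @param ds a \linkS4class{BehaviorDataset}.
#' @param measures measure names to require (default: the whole battery).
#' @return A \linkS4class{BehaviorDataset} of complete cases.
#' @export
completeCaseSubset <- function(ds, measures = measureNames(ds)) {
    bad <- setdiff(measures, measureNames(ds))
    if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
    A <- assay(ds, "measures")[measures, , drop = FALSE]
    keep <- colSums(is.na(A)) == 0L
    if (!any(keep)) stop("no complete cases for the requested measures")
    out <- ds[measures, keep]
    methods::validObject(out)
    out
}

#' Per-cohort missingness report
#'
#' Counts missing cells per cohort and measure; useful for checking block-wise
#' missingness designs where some cohorts did not run a subset of tests.
#'
#' @param ds a \linkS4class{BehaviorDataset}.
#' @return data.frame with one row per cohort and one column per measure
#'   holding the count of missing cells, plus an \code{n_animals} column.
#' @export
missingnessReport <- function(ds) {
    co <- cohorts(ds)
    co[is.na(co)] <- "(none)"
    A <- is.na(assay(ds, "measures"))
    cos <- unique(co)
    out <- data.frame(cohort = cos, n_animals = NA_integer_,
                      stringsAsFactors = FALSE)
    for (m in rownames(A)) out[[m]] <- NA_integer_
    for (i in seq_along(cos)) {
        sel <- co == cos[i]
        out$n_animals[i] <- sum(sel)
        out[i, rownames(A)] <- as.integer(rowSums(A[, sel, drop = FALSE]))
    }
    out
}
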