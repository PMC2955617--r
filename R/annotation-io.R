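# Chip layouts, substrate->kinase annotation, kinase metadata and
# kinase->pathway sets: constructors, validators, readers and writers.

CONTROL_TYPES <- c("positive", "negative", "none")

#' Construct a validated chip layout
#'
#' A chip layout records the physical geometry and identity of every spot on
#' a peptide kinase-substrate array: substrate spots (each substrate printed
#' in `n_replicates` replicate spots) and positive/negative control spots.
#'
#' @param spots data.frame with columns `spot_id`, `substrate_id`
#'   (`NA` for control spots), `replicate_idx` (0-based), `block`, `row`,
#'   `col` (0-based grid coordinates) and `control_type`
#'   (`"positive"`, `"negative"` or `"none"`).
#' @param chip_id character scalar identifying the chip design.
#' @return An object of class `chip_layout`: a list with elements `chip_id`,
#'   `spots` (the validated data.frame), `n_substrates`, `n_replicates`,
#'   `n_controls` (named vector with `positive` and `negative` counts).
#' @examples
#' lay <- chip_layout(data.frame(
#'   spot_id = c("s1", "s2"), substrate_id = c("A", NA),
#'   replicate_idx = c(0L, 0L), block = c(0L, 0L), row = c(0L, 0L),
#'   col = c(0L, 1L), control_type = c("none", "negative")))
#' lay$n_substrates
#' @export
chip_layout <- function(spots, chip_id = "chip") {
  assert_columns(spots, c("spot_id", "substrate_id", "replicate_idx",
                          "block", "row", "col", "control_type"),
                 "layout table")
  spots$substrate_id <- as.character(spots$substrate_id)
  spots$substrate_id[spots$substrate_id %in% c("", "NA")] <- NA_character_
  spots$spot_id <- as.character(spots$spot_id)
  spots$control_type <- as.character(spots$control_type)

  bad_ct <- setdiff(unique(spots$control_type), CONTROL_TYPES)
  if (length(bad_ct) > 0) {
    stop_ks("unknown control_type value(s): %s", paste(bad_ct, collapse = ", "))
  }
  if (anyDuplicated(spots$spot_id)) stop_ks("duplicate spot_id in layout")
  coord <- paste(spots$block, spots$row, spots$col, sep = ":")
  if (anyDuplicated(coord)) {
    stop_ks("layout format error: duplicate grid coordinates (block,row,col) at %s",
            coord[duplicated(coord)][1])
  }
  is_ctrl <- spots$control_type != "none"
  if (any(!is_ctrl & is.na(spots$substrate_id))) {
    stop_ks("substrate spots must carry a substrate_id")
  }
  if (any(is_ctrl & !is.na(spots$substrate_id))) {
    stop_ks("control spots must not carry a substrate_id")
  }

  sub <- spots[!is_ctrl, , drop = FALSE]
  reps <- table(sub$substrate_id)
  n_rep <- if (nrow(sub) > 0) as.integer(reps[1]) else 0L
  if (nrow(sub) > 0 && any(reps != n_rep)) {
    off <- names(reps)[reps != n_rep][1]
    stop_ks("validation error: substrate %s has %d replicate spots, expected %d",
            off, as.integer(reps[off]), n_rep)
  }
  if (any(sub$replicate_idx < 0 | sub$replicate_idx >= n_rep)) {
    stop_ks("replicate_idx must lie in [0, n_replicates)")
  }

  structure(list(
    chip_id = chip_id,
    spots = spots,
    n_substrates = length(reps),
    n_replicates = n_rep,
    n_controls = c(positive = sum(spots$control_type == "positive"),
                   negative = sum(spots$control_type == "negative"))
  ), class = "chip_layout")
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("chip_layout '%s': %d substrates x %d replicates, %d positive / %d negative controls (%d spots)\n",
              x$chip_id, x$n_substrates, x$n_replicates,
              x$n_controls[["positive"]], x$n_controls[["negative"]],
              nrow(x$spots)))
  invisible(x)
}

#' Default peptide-array layout
#'
#' Generates the default chip design used throughout the package: 1024
#' distinct kinase substrates printed in triplicate plus 16 negative and 16
#' positive control spots, laid out across 20x20 blocks.  Control spots are
#' printed once each (the replicate structure of controls is not part of the
#' published chip description).
#'
#' @param n_substrates number of distinct substrates.
#' @param n_replicates replicate spots per substrate.
#' @param n_negative,n_positive number of negative / positive control spots.
#' @param chip_id chip identifier.
#' @return A [chip_layout()].
#' @examples
#' lay <- default_layout()
#' lay$n_substrates   # 1024
#' @export
default_layout <- function(n_substrates = 1024, n_replicates = 3,
                           n_negative = 16, n_positive = 16,
                           chip_id = "pepchip-1024") {
  n_sub_spots <- n_substrates * n_replicates
  n_total <- n_sub_spots + n_negative + n_positive
  per_block <- 400L  # 20 x 20
  idx <- seq_len(n_total) - 1L
  block <- idx %/% per_block
  within <- idx %% per_block
  substrate_id <- c(rep(sprintf("S%04d", seq_len(n_substrates)),
                        each = n_replicates),
                    rep(NA_character_, n_negative + n_positive))
  replicate_idx <- c(rep(seq_len(n_replicates) - 1L, times = n_substrates),
                     rep(0L, n_negative + n_positive))
  control_type <- c(rep("none", n_sub_spots),
                    rep("negative", n_negative), rep("positive", n_positive))
  spots <- data.frame(
    spot_id = sprintf("spot%05d", seq_len(n_total)),
    substrate_id = substrate_id,
    replicate_idx = replicate_idx,
    block = block,
    row = within %/% 20L,
    col = within %% 20L,
    control_type = control_type,
    stringsAsFactors = FALSE
  )
  chip_layout(spots, chip_id = chip_id)
}

#' Read a chip layout from a TSV file
#'
#' The file must have the columns `spot_id`, `substrate_id`, `replicate_idx`,
#' `block`, `row`, `col`, `control_type` (coordinates 0-based; empty
#' `substrate_id` for control spots).
#'
#' @param path path to a tab-separated layout file.
#' @param chip_id chip identifier; defaults to the file name.
#' @return A validated [chip_layout()].
#' @seealso [write_layout()]
#' @export
load_layout <- function(path, chip_id = NULL) {
  df <- read_tsv_file(path, "layout file")
  chip_layout(df, chip_id = chip_id %||%
                sub("\\.[^.]*$", "", basename(path)))
}

#' Write a chip layout to a TSV file
#'
#' Inverse of [load_layout()]: `load_layout(write_layout(lay, f))` returns a
#' layout identical to `lay`.
#'
#' @param layout a [chip_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  write_tsv_file(layout$spots, path)
}

#' Construct a substrate->kinase annotation
#'
#' Maps each annotated substrate to the set of kinases known to
#' phosphorylate it.  The mapping is many-to-many: one substrate may report
#' on several kinases (such substrates contribute fully to each), and
#' substrates may be unannotated.
#'
#' @param df data.frame with columns `substrate_id`, `kinase_id`
#'   (one row per mapping).
#' @return Object of class `substrate_annotation`: list with `map` (named
#'   list substrate_id -> character vector of kinase ids) and `kinases`
#'   (sorted vector of all kinase ids appearing in the map).
#' @export
substrate_annotation <- function(df) {
  assert_columns(df, c("substrate_id", "kinase_id"), "substrate annotation")
  df$substrate_id <- as.character(df$substrate_id)
  df$kinase_id <- as.character(df$kinase_id)
  df <- unique(df[order(df$substrate_id, df$kinase_id), , drop = FALSE])
  map <- split(df$kinase_id, df$substrate_id)
  if (any(lengths(map) == 0)) stop_ks("annotated substrates must map to >=1 kinase")
  structure(list(map = map, kinases = sort(unique(df$kinase_id))),
            class = "substrate_annotation")
}

#' Construct a kinase metadata table
#'
#' @param df data.frame with columns `kinase_id`, `name`, `description`,
#'   `categories` (comma-separated tags, e.g. `"cell_cycle"`), `known_drugs`
#'   (comma-separated, informational).  Missing optional columns are filled
#'   with empty strings.
#' @return data.frame of class `kinase_table` with a list-column
#'   `category_list`.
#' @export
kinase_table <- function(df) {
  assert_columns(df, "kinase_id", "kinase table")
  df$kinase_id <- as.character(df$kinase_id)
  if (anyDuplicated(df$kinase_id)) stop_ks("kinase_id must be unique")
  for (col in c("name", "description", "categories", "known_drugs")) {
    if (is.null(df[[col]])) df[[col]] <- ""
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$category_list <- lapply(strsplit(df$categories, ","), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  class(df) <- c("kinase_table", "data.frame")
  df
}

#' Construct a kinase->pathway annotation
#'
#' @param df data.frame with columns `pathway_id`, `kinase_id` (one row per
#'   membership) and optionally `pathway_name`.
#' @param kinases optional [kinase_table()]; if given, every member kinase
#'   must exist in it.
#' @return Object of class `pathway_annotation`: list with `sets` (named
#'   list pathway_id -> kinase ids) and `names` (named display names).
#' @export
pathway_annotation <- function(df, kinases = NULL) {
  assert_columns(df, c("pathway_id", "kinase_id"), "pathway annotation")
  df$pathway_id <- as.character(df$pathway_id)
  df$kinase_id <- as.character(df$kinase_id)
  sets <- lapply(split(df$kinase_id, df$pathway_id), function(x) sort(unique(x)))
  if (any(lengths(sets) == 0)) stop_ks("validation error: empty pathway")
  if (!is.null(kinases)) {
    unknown <- setdiff(unlist(sets), kinases$kinase_id)
    if (length(unknown) > 0) {
      stop_ks("validation error: pathway member kinase(s) absent from kinase table: %s",
              paste(unknown, collapse = ", "))
    }
  }
  nm <- if ("pathway_name" %in% names(df)) {
    tapply(df$pathway_name, df$pathway_id, function(x) as.character(x[1]))
  } else {
    setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, names = nm[names(sets)]),
            class = "pathway_annotation")
}

#' Load substrate, kinase and pathway annotation tables
#'
#' Reads and cross-validates the three annotation inputs: the
#' substrate->kinase mapping (`substrate_id`, `kinase_id`), the kinase
#' metadata table (`kinase_id`, `name`, `description`, `categories`,
#' `known_drugs`) and the kinase->pathway memberships (`pathway_id`,
#' `kinase_id`[, `pathway_name`]).  Every kinase referenced by the substrate
#' or pathway table must exist in the kinase table.  The number of layout
#' substrates left unannotated (when `layout` is supplied) is reported with
#' a message.
#'
#' @param substrate_path,kinase_path,pathway_path TSV file paths.
#' @param layout optional [chip_layout()] to validate substrate ids against.
#' @return list with elements `substrates` ([substrate_annotation()]),
#'   `kinases` ([kinase_table()]) and `pathways` ([pathway_annotation()]).
#' @export
load_annotations <- function(substrate_path, kinase_path, pathway_path,
                             layout = NULL) {
  sub_df <- read_tsv_file(substrate_path, "substrate annotation file")
  kin_df <- read_tsv_file(kinase_path, "kinase table file")
  pw_df <- read_tsv_file(pathway_path, "pathway annotation file")

  kin <- kinase_table(kin_df)
  sub <- substrate_annotation(sub_df)
  unknown <- setdiff(sub$kinases, kin$kinase_id)
  if (length(unknown) > 0) {
    stop_ks("validation error: kinase_id in substrate table absent from kinase table: %s",
            paste(unknown, collapse = ", "))
  }
  pw <- pathway_annotation(pw_df, kinases = kin)

  if (!is.null(layout)) {
    subs <- unique(layout$spots$substrate_id)
    subs <- subs[!is.na(subs)]
    missing <- setdiff(names(sub$map), subs)
    if (length(missing) > 0) {
      stop_ks("validation error: annotated substrate(s) absent from layout: %s",
              paste(head(missing, 5), collapse = ", "))
    }
    n_unannot <- length(setdiff(subs, names(sub$map)))
    message(sprintf("%d of %d layout substrates are unannotated", n_unannot,
                    length(subs)))
  }
  list(substrates = sub, kinases = kin, pathways = pw)
}

#' Import spot intensities from a GenePix results (GPR) file
#'
#' GPR files are tab-separated ATF files: an `ATF` version line, a line
#' giving the number of optional header records, the header records
#' (`"Key=Value"`), then the data table.  The `Name` column is mapped to
#' `substrate_id` and the chosen foreground column (default
#' `"F532 Median"`) to `raw_intensity`; `Block`, `Row` and `Column` are
#' converted to 0-based coordinates.
#'
#' @param path path to a GPR file.
#' @param value_column name of the intensity column to import.
#' @return data.frame with columns `substrate_id`, `block`, `row`, `col`,
#'   `raw_intensity`.
#' @export
read_gpr <- function(path, value_column = "F532 Median") {
  if (!file.exists(path)) stop_ks("GPR file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !grepl("^ATF", lines[1])) {
    stop_ks("not an ATF/GPR file (missing ATF header): %s", path)
  }
  counts <- strsplit(trimws(lines[2]), "[\t ]+")[[1]]
  n_header <- as.integer(counts[1])
  tab_start <- 2L + n_header + 1L
  df <- read.delim(text = paste(lines[tab_start:length(lines)], collapse = "\n"),
                   sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  assert_columns(df, c("Block", "Row", "Column", "Name", value_column),
                 "GPR data table")
  data.frame(
    substrate_id = as.character(df$Name),
    block = as.integer(df$Block) - 1L,
    row = as.integer(df$Row) - 1L,
    col = as.integer(df$Column) - 1L,
    raw_intensity = as.numeric(df[[value_column]]),
    stringsAsFactors = FALSE
  )
}

#' Read pathway sets from a GMT file
#'
#' One pathway per line: `pathway_id <TAB> description <TAB> member ...`.
#'
#' @param path path to a GMT file.
#' @param kinases optional [kinase_table()] for validation.
#' @return A [pathway_annotation()].
#' @export
read_gmt <- function(path, kinases = NULL) {
  if (!file.exists(path)) stop_ks("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop_ks("GMT line %d has fewer than 3 fields", which(bad)[1])
  df <- do.call(rbind, lapply(parts, function(p) {
    data.frame(pathway_id = p[1], pathway_name = p[2],
               kinase_id = p[-(1:2)], stringsAsFactors = FALSE)
  }))
  pathway_annotation(df, kinases = kinases)
}
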