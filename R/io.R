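# Delimited-text I/O for genealogies and interaction tables, fixture
# generation, and run manifests.

#' Read a genealogy table
#'
#' Reads a delimited genealogy (columns `id`, `sex`, `age_class`,
#' `mother_id`, `father_id`, `litter_id`, `group_id`, `location_id`,
#' `sampled`; empty string = absent; header required; comma- or
#' tab-separated by extension). Parent ids that do not match any row are
#' materialized as unsampled founders of unknown sex/age with a warning,
#' mirroring genealogy reconstruction where unsampled parents are
#' inferred. Duplicate ids are a hard error.
#'
#' @param path file path (`.csv` comma-separated, otherwise tab).
#' @return a [pedigree()].
#' @export
read_genealogy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   na.strings = "", quote = "\"", comment.char = "")
  missing_cols <- setdiff(c("id", "sex"), names(df))
  if (length(missing_cols))
    stop("genealogy header lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if ("sampled" %in% names(df))
    df$sampled <- toupper(df$sampled) %in% c("TRUE", "T", "1", "YES")
  dangling <- setdiff(
    c(df$mother_id[!is.na(df$mother_id)], df$father_id[!is.na(df$father_id)]),
    df$id)
  if (length(dangling)) {
    warning("materializing ", length(dangling),
            " dangling parent id(s) as unsampled founders: ",
            paste(head(dangling, 5L), collapse = ", "),
            if (length(dangling) > 5L) ", ..." else "")
    mom_ids <- unique(df$mother_id[!is.na(df$mother_id)])
    extra <- data.frame(id = dangling,
                        sex = ifelse(dangling %in% mom_ids, "F", "M"),
                        age_class = "unknown", mother_id = NA_character_,
                        father_id = NA_character_, litter_id = NA_character_,
                        group_id = NA_character_,
                        location_id = NA_character_, sampled = FALSE,
                        stringsAsFactors = FALSE)
    for (col in setdiff(names(extra), names(df))) df[[col]] <- NA
    df <- rbind(df[, GENEALOGY_COLUMNS[GENEALOGY_COLUMNS %in% names(df)],
                   drop = FALSE][, , drop = FALSE],
                extra[, GENEALOGY_COLUMNS[GENEALOGY_COLUMNS %in% names(df)],
                      drop = FALSE])
  }
  pedigree(df)
}

#' Write a genealogy table
#'
#' Inverse of [read_genealogy()]: absent values become empty strings.
#'
#' @param ped a [pedigree()].
#' @param path output path (`.csv` comma-separated, otherwise tab).
#' @export
write_genealogy <- function(ped, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- ped$individuals
  df$sampled <- ifelse(df$sampled, "TRUE", "FALSE")
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write dyadic interaction tables
#'
#' CSV with columns `id_a`, `id_b`, `season`, `count`.
#'
#' @param path file path.
#' @export
read_interactions <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",",
                   colClasses = c("character", "character", "character",
                                  "integer"))
  need <- c("id_a", "id_b", "season", "count")
  if (!all(need %in% names(df)))
    stop("interaction header must contain: ", paste(need, collapse = ", "))
  if (any(df$id_a == df$id_b)) stop("self-interaction rows are not allowed")
  df
}

#' @rdname read_interactions
#' @param interactions data.frame to write.
#' @export
write_interactions <- function(interactions, path) {
  write.table(interactions, path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, master seed, package version, a hash of the
#' configuration and checksums of input files, so that deterministic runs
#' can be reproduced byte-identically.
#'
#' @param path output JSON path.
#' @param command short command label.
#' @param seed master seed.
#' @param config optional configuration object (hashed after JSON
#'   serialization).
#' @param inputs character vector of input file paths to checksum.
#' @export
write_run_manifest <- function(path, command, seed, config = NULL,
                               inputs = character()) {
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                                digits = NA), tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(
    command = command, seed = seed, config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("matesys")),
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Generate deterministic fixture datasets
#'
#' Small, fully synthetic datasets used across examples and tests:
#' `trio` (mother, father, one pup), `inbred-family` (a family containing
#' exactly one father-daughter parent pair), `morocco-like`,
#' `ukraine-like` and `italy-like` (structured populations subsampled to
#' the genotyped cohort sizes 196, 286 and 44 respectively; the
#' ukraine-like preset spans two locations with high philopatry), and
#' `interactions` (a grouped population plus its dyadic proximity
#' counts). Identical seeds give identical files.
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return character vector of file paths written.
#' @export
make_fixtures <- function(kind = c("trio", "inbred-family", "morocco-like",
                                   "ukraine-like", "italy-like",
                                   "interactions"),
                          seed = 1L, dir = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- file.path(dir, paste0(gsub("-", "_", kind), ".tsv"))
  ped <- switch(
    kind,
    "trio" = pedigree(data.frame(
      id = c("mom", "dad", "pup1"), sex = c("F", "M", "F"),
      age_class = c("adult", "adult", "pup"),
      mother_id = c(NA, NA, "mom"), father_id = c(NA, NA, "dad"),
      litter_id = c(NA, NA, "L1"), stringsAsFactors = FALSE)),
    "inbred-family" = inbred_family_pedigree(),
    "morocco-like" = subsample_pedigree(
      simulate_structured_population(sim_config(
        scenario = "structured", n_founders = 120L, target_pop_size = 120L,
        n_generations = 4L, seed = substream_seed(seed, 0L, "morocco"),
        structured_knobs = list(male_skew = 0.8, philopatry = 0.6,
                                n_groups = 11L, n_locations = 1L))),
      196L, seed = substream_seed(seed, 1L, "morocco")),
    "ukraine-like" = subsample_pedigree(
      simulate_structured_population(sim_config(
        scenario = "structured", n_founders = 200L, target_pop_size = 200L,
        n_generations = 4L, seed = substream_seed(seed, 0L, "ukraine"),
        structured_knobs = list(male_skew = 1.0, philopatry = 0.9,
                                n_groups = 3L, n_locations = 2L,
                                female_dispersal_bias = 0.8))),
      286L, seed = substream_seed(seed, 1L, "ukraine")),
    "italy-like" = subsample_pedigree(
      simulate_structured_population(sim_config(
        scenario = "structured", n_founders = 60L, target_pop_size = 60L,
        n_generations = 4L, seed = substream_seed(seed, 0L, "italy"),
        structured_knobs = list(male_skew = 0.5, philopatry = 0.6,
                                n_groups = 6L, n_locations = 1L))),
      44L, seed = substream_seed(seed, 1L, "italy")),
    "interactions" = simulate_structured_population(sim_config(
      scenario = "structured", n_founders = 60L, target_pop_size = 60L,
      n_generations = 3L, seed = substream_seed(seed, 0L, "interactions"),
      structured_knobs = list(philopatry = 0.9, n_groups = 4L,
                              n_locations = 1L))))
  files <- character(0)
  write_genealogy(ped, out)
  files <- c(files, out)
  if (kind == "interactions") {
    tab <- simulate_interactions(
      ped, params = list(seasons = c("s1", "s2")),
      seed = substream_seed(seed, 1L, "interactions"))
    ipath <- file.path(dir, "interactions.csv")
    write_interactions(tab, ipath)
    files <- c(files, ipath)
  }
  mpath <- file.path(dir, paste0(gsub("-", "_", kind), "_manifest.json"))
  write_run_manifest(mpath, command = paste0("fixtures:", kind), seed = seed,
                     inputs = files)
  files <- c(files, mpath)
  files
}

# family with exactly one father-daughter parent pair (the predominant
# close-inbreeding type)
inbred_family_pedigree <- function() {
  pedigree(data.frame(
    id = c("F0", "M0", "D1", "S1", "X2"),
    sex = c("F", "M", "F", "M", "M"),
    age_class = c("adult", "adult", "adult", "adult", "pup"),
    mother_id = c(NA, NA, "F0", "F0", "D1"),
    father_id = c(NA, NA, "M0", "M0", "M0"),
    litter_id = c(NA, NA, "L1", "L1", "L2"),
    stringsAsFactors = FALSE))
}
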