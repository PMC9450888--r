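#' Rule-based classification of focus substructures
#'
#' Verbal class definitions ("one BRCA1 spot encapsulated by multiple
#' 53BP1 spots") are made operational as explicit count predicates over
#' (site count, per-partner counts, encapsulation flag). Rule sets are
#' plain tables — shipped as editable YAML under `inst/extdata` — and are
#' validated for exhaustiveness and mutual exclusivity over the reachable
#' count space before use. A manual mode (export crops, ingest a
#' hand-label CSV) is available through [crop_structure()] and
#' [ingest_manual_labels()].
#'
#' @name classification
NULL

cap2 <- function(n) pmin(n, 2L)   # count space: 0 / 1 / "multiple" (2)

#' Build a class rule set from a rule table
#'
#' Each row is a predicate: `site_min/site_max`, `partner_min/partner_max`,
#' `partner2_min/partner2_max` (counts, `Inf` allowed for max), an
#' `encapsulated` requirement (`TRUE`, `FALSE`, or `NA` = don't care) and
#' the resulting `class`. Validation enumerates the reachable count grid
#' (counts capped at "multiple") and requires exactly one matching rule per
#' cell.
#'
#' @param rules data frame of rules.
#' @param taxonomy name of the taxonomy.
#' @param min_satellites,min_arc_deg encapsulation parameters (see
#'   [encapsulation_test()]).
#' @return a validated object of class `exm_class_rules`.
#' @export
class_rule_set <- function(rules, taxonomy = "custom", min_satellites = 3L,
                           min_arc_deg = 180) {
  need <- c("site_min", "site_max", "partner_min", "partner_max", "class")
  miss <- setdiff(need, names(rules))
  if (length(miss))
    stop("rule table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"partner2_min" %in% names(rules)) {
    rules$partner2_min <- 0; rules$partner2_max <- Inf
  }
  if (!"encapsulated" %in% names(rules)) rules$encapsulated <- NA
  rs <- structure(list(taxonomy = taxonomy, rules = rules,
                       min_satellites = min_satellites,
                       min_arc_deg = min_arc_deg),
                  class = "exm_class_rules")
  validate_class_rules(rs)
  rs
}

match_rules <- function(rules, site, partner, partner2, enc) {
  which(
    site >= rules$site_min & site <= rules$site_max &
      partner >= rules$partner_min & partner <= rules$partner_max &
      partner2 >= rules$partner2_min & partner2 <= rules$partner2_max &
      (is.na(rules$encapsulated) | rules$encapsulated == enc)
  )
}

#' Validate a rule set for exhaustiveness and mutual exclusivity
#'
#' @param rs an `exm_class_rules` object.
#' @return `TRUE` invisibly; errors naming the offending cell otherwise.
#' @export
validate_class_rules <- function(rs) {
  grid <- expand.grid(site = 1:2, partner = 0:2, partner2 = 0:2,
                      enc = c(FALSE, TRUE))
  # encapsulation can only hold with enough satellites
  grid <- grid[!(grid$enc & grid$partner < min(rs$min_satellites, 2)), ]
  for (i in seq_len(nrow(grid))) {
    m <- match_rules(rs$rules, grid$site[i], grid$partner[i],
                     grid$partner2[i], grid$enc[i])
    if (length(m) == 0L)
      stop(sprintf(
        "rule gap: no class for site=%d partner=%d partner2=%d enc=%s",
        grid$site[i], grid$partner[i], grid$partner2[i], grid$enc[i]),
        call. = FALSE)
    if (length(unique(rs$rules$class[m])) > 1L)
      stop(sprintf(
        "ambiguous rules: site=%d partner=%d partner2=%d enc=%s matches classes %s",
        grid$site[i], grid$partner[i], grid$partner2[i], grid$enc[i],
        paste(unique(rs$rules$class[m]), collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Default two-channel taxonomy (site = BRCA1, partner = 53BP1)
#'
#' Class 1: core site spot(s) only. Class 2: one site + one partner spot.
#' Class 3: multiple site spots + one partner. Class 4: multiple site and
#' multiple partner spots, or a single site spot whose multiple partners
#' fail the encapsulation test. Class 5: one site spot encapsulated by
#' multiple partner satellites.
#'
#' @param min_satellites,min_arc_deg encapsulation parameters.
#' @return an `exm_class_rules`.
#' @export
two_channel_rules <- function(min_satellites = 3L, min_arc_deg = 180) {
  rules <- rbind(
    data.frame(site_min = 1, site_max = Inf, partner_min = 0, partner_max = 0,
               encapsulated = NA, class = 1L),
    data.frame(site_min = 1, site_max = 1, partner_min = 1, partner_max = 1,
               encapsulated = NA, class = 2L),
    data.frame(site_min = 2, site_max = Inf, partner_min = 1, partner_max = 1,
               encapsulated = NA, class = 3L),
    data.frame(site_min = 2, site_max = Inf, partner_min = 2, partner_max = Inf,
               encapsulated = NA, class = 4L),
    data.frame(site_min = 1, site_max = 1, partner_min = 2, partner_max = Inf,
               encapsulated = FALSE, class = 4L),
    data.frame(site_min = 1, site_max = 1, partner_min = 2, partner_max = Inf,
               encapsulated = TRUE, class = 5L)
  )
  class_rule_set(rules, taxonomy = "two_channel",
                 min_satellites = min_satellites, min_arc_deg = min_arc_deg)
}

#' Default three-channel taxonomy (site = RAD51; partners 53BP1, BRCA1)
#'
#' RAD51 is defined as the structure centre; the ten classes enumerate
#' (RAD51 single/multiple) x (53BP1 absent/single/multiple) x (BRCA1
#' absent/present), with encapsulation splitting the all-three multi-spot
#' cell. The mapping is a reconstruction constrained by the pinned classes
#' (class 4 = multiple RAD51 + multiple 53BP1 without BRCA1; classes 7–9
#' contain all three proteins; class 9 = multiple RAD51 with BRCA1,
#' encapsulated by multiple 53BP1) and is shipped as an editable YAML
#' rules file (`system.file("extdata", "rules_three_channel.yaml",
#' package = "exmfoci")`).
#'
#' @param min_satellites,min_arc_deg encapsulation parameters.
#' @return an `exm_class_rules`.
#' @export
three_channel_rules <- function(min_satellites = 3L, min_arc_deg = 180) {
  r <- function(s1, s2, p1, p2, b1, b2, enc, cls)
    data.frame(site_min = s1, site_max = s2, partner_min = p1,
               partner_max = p2, partner2_min = b1, partner2_max = b2,
               encapsulated = enc, class = cls)
  rules <- rbind(
    r(1, 1, 0, 0, 0, 0, NA, 1L),       # single RAD51 only
    r(1, 1, 1, 1, 0, 0, NA, 2L),       # single RAD51 + one 53BP1
    r(1, 1, 2, Inf, 0, 0, NA, 3L),     # single RAD51 + multiple 53BP1
    r(2, Inf, 2, Inf, 0, 0, NA, 4L),   # multi RAD51 + multi 53BP1
    r(2, Inf, 0, 0, 0, 0, NA, 5L),     # multiple RAD51 only
    r(1, Inf, 0, 0, 1, Inf, NA, 6L),   # RAD51 + BRCA1, no 53BP1
    r(1, 1, 1, Inf, 1, Inf, NA, 7L),   # single RAD51 + BRCA1 + 53BP1
    r(2, Inf, 1, 1, 1, Inf, NA, 8L),   # multi RAD51 + BRCA1 + one 53BP1
    r(2, Inf, 2, Inf, 1, Inf, FALSE, 8L), # ... multi 53BP1, no shell
    r(2, Inf, 2, Inf, 1, Inf, TRUE, 9L),  # ... encapsulating 53BP1 shell
    r(2, Inf, 1, 1, 0, 0, NA, 10L)     # multi RAD51 + one 53BP1
  )
  class_rule_set(rules, taxonomy = "three_channel",
                 min_satellites = min_satellites, min_arc_deg = min_arc_deg)
}

#' Load a rule set from a YAML file
#'
#' @param path YAML file with fields `taxonomy`, `min_satellites`,
#'   `min_arc_deg` and a `rules` list of rows (use `.inf` for an unbounded
#'   max).
#' @return an `exm_class_rules`.
#' @export
load_class_rules <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(y$rules, function(r) {
    as.data.frame(lapply(r, function(v)
      if (identical(v, "inf")) Inf else if (is.null(v)) NA else v))
  })
  rules <- do.call(rbind, rows)
  if (!"encapsulated" %in% names(rules)) rules$encapsulated <- NA
  rules$encapsulated <- as.logical(rules$encapsulated)
  class_rule_set(rules, taxonomy = y$taxonomy %||% "custom",
                 min_satellites = y$min_satellites %||% 3L,
                 min_arc_deg = y$min_arc_deg %||% 180)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# counts -> class under the default two-channel rules (fast path used by
# the simulator's self-check)
classify_counts_two_channel <- function(site, partner, enc) {
  if (partner == 0) 1L
  else if (site == 1 && partner == 1) 2L
  else if (site >= 2 && partner == 1) 3L
  else if (site >= 2 && partner >= 2) 4L
  else if (enc) 5L else 4L
}

classify_counts_three_channel <- function(site, partner, partner2, enc) {
  if (partner2 == 0) {
    if (site == 1) {
      if (partner == 0) 1L else if (partner == 1) 2L else 3L
    } else {
      if (partner == 0) 5L else if (partner == 1) 10L else 4L
    }
  } else {
    if (partner == 0) 6L
    else if (site == 1) 7L
    else if (partner == 1) 8L
    else if (enc) 9L else 8L
  }
}

#' Classify an assembled structure
#'
#' Applies a rule set to the structure's per-channel counts; the
#' encapsulation flag is evaluated (only when some rule needs it) from the
#' core position and the partner-channel spot positions via
#' [encapsulation_test()]. Deterministic and invariant to spot order and
#' to rigid motion of the structure.
#'
#' @param structure an `exm_structure` from [assemble_structures()].
#' @param rules an `exm_class_rules` (default [two_channel_rules()]).
#' @param partner_channel channel whose spots form the encapsulating
#'   shell (default: first partner channel).
#' @return the structure with `class_label` set.
#' @export
classify_structure <- function(structure, rules = two_channel_rules(),
                               partner_channel = NULL) {
  stopifnot(inherits(structure, "exm_structure"),
            inherits(rules, "exm_class_rules"))
  chs <- names(structure$members)
  if (is.null(partner_channel) && length(chs)) partner_channel <- chs[1]
  site_n <- structure$counts[["site"]]
  partner_n <- if (!is.null(partner_channel) && partner_channel %in% chs)
    nrow(structure$members[[partner_channel]]) else 0L
  other <- if (length(chs)) setdiff(chs, partner_channel) else character(0)
  partner2_n <- if (length(other))
    sum(vapply(other, function(ch) nrow(structure$members[[ch]]),
               integer(1))) else 0L
  enc <- FALSE
  needs_enc <- any(!is.na(rules$rules$encapsulated))
  if (needs_enc && partner_n >= rules$min_satellites &&
      !is.null(partner_channel) && partner_channel %in% chs) {
    sat <- as.matrix(structure$members[[partner_channel]][, c("x", "y", "z")])
    enc <- encapsulation_test(structure$core, sat,
                              min_satellites = rules$min_satellites,
                              min_arc_deg = rules$min_arc_deg)
  }
  m <- match_rules(rules$rules, site_n, partner_n, partner2_n, enc)
  if (length(m) == 0L)
    stop(sprintf(
      "no rule covers counts site=%d, partner=%d, partner2=%d, enc=%s",
      site_n, partner_n, partner2_n, enc), call. = FALSE)
  structure$class_label <- rules$rules$class[m[1]]
  structure$encapsulated <- enc
  structure
}

#' Classify with the three-channel (RAD51-centred) taxonomy
#'
#' @param structure an `exm_structure` whose site channel is RAD51 and
#'   whose members hold the 53BP1 (`partner`) and BRCA1 (`partner2`)
#'   channels.
#' @param rules rule set (default [three_channel_rules()]).
#' @return the structure with `class_label` in 1..10.
#' @export
classify_three_channel <- function(structure, rules = three_channel_rules()) {
  classify_structure(structure, rules, partner_channel = "partner")
}

#' Default core–satellite distance bins
#'
#' Post-expansion µm bins used to subclassify encapsulated (class 5)
#' structures by the distance of the 53BP1 shell from the core BRCA1 spot:
#' contracted `< 0.5`, intermediate `0.5–1.8`, control-like `1.8–2`,
#' extended `2–2.5`.
#'
#' @return data frame with `label`, `min_um`, `max_um`.
#' @export
default_distance_bins <- function() {
  data.frame(label = c("contracted", "intermediate", "control_like",
                       "extended"),
             min_um = c(0, 0.5, 1.8, 2.0),
             max_um = c(0.5, 1.8, 2.0, 2.5),
             stringsAsFactors = FALSE)
}

#' Subclassify an encapsulated structure by shell distance
#'
#' The representative distance is the median core-to-satellite distance of
#' the partner spots; the label is the containing bin (intervals are
#' `(min, max]`). A distance beyond all bins returns `"overflow"` with a
#' warning.
#'
#' @param structure a classified `exm_structure` (class 5).
#' @param bins bin table as in [default_distance_bins()].
#' @param partner_channel shell channel (default first).
#' @return list with `label` and `distance_um`.
#' @export
subclassify_by_distance <- function(structure, bins = default_distance_bins(),
                                    partner_channel = NULL) {
  stopifnot(inherits(structure, "exm_structure"))
  chs <- names(structure$members)
  if (is.null(partner_channel)) partner_channel <- chs[1]
  m <- structure$members[[partner_channel]]
  if (nrow(m) == 0L)
    stop("structure has no partner spots to measure", call. = FALSE)
  d_um <- stats::median(m$dist_nm) / 1000
  hit <- which(d_um > bins$min_um & d_um <= bins$max_um)
  if (length(hit) == 0L) {
    warning(sprintf("distance %.3g um outside all bins; overflow", d_um))
    return(list(label = "overflow", distance_um = d_um))
  }
  list(label = bins$label[hit[1]], distance_um = d_um)
}

#' Continuity of an accumulation within a structure crop
#'
#' The crop is thresholded at `intensity_fraction` of its maximum; the
#' accumulation is `"continuous"` iff at least two member-spot centres
#' fall inside one connected foreground component (6-connectivity).
#'
#' @param crop a [voxel_grid()] crop of the structure.
#' @param member_spots data frame of member spots with `x, y, z` in nm in
#'   the crop's coordinate frame.
#' @param intensity_fraction threshold fraction of the crop maximum
#'   (default 0.5).
#' @return `"continuous"` or `"discontinuous"`.
#' @export
continuity_test <- function(crop, member_spots, intensity_fraction = 0.5) {
  stopifnot(inherits(crop, "exm_voxel_grid"))
  if (nrow(member_spots) < 2L)
    stop("continuity requires at least 2 member spots", call. = FALSE)
  thr <- intensity_fraction * max(crop$data)
  lab <- label_components_3d(crop$data >= thr)
  idx <- ceiling(as.matrix(member_spots[, c("x", "y", "z")]) /
                   matrix(crop$voxel_size, nrow(member_spots), 3,
                          byrow = TRUE))
  d <- dim(crop$data)
  idx <- pmin(pmax(idx, 1L), matrix(d, nrow(idx), 3, byrow = TRUE))
  comp <- lab[idx]
  comp <- comp[comp > 0L]
  if (length(comp) >= 2L && any(table(comp) >= 2L)) "continuous"
  else "discontinuous"
}

#' Crop a volume around a structure core
#'
#' Axis-aligned cube centred on the core, zero-padded at image borders
#' (default edge 5 µm, the crop-box size used for manual review).
#'
#' @param vg a [voxel_grid()].
#' @param core_nm length-3 core position in nm.
#' @param box_edge_um cube edge in µm (default 5).
#' @return a [voxel_grid()] crop.
#' @export
crop_structure <- function(vg, core_nm, box_edge_um = 5) {
  crop_box(vg, core_nm, box_edge_um * 1000)
}

#' Ingest manual class labels for exported crops
#'
#' Manual-mode companion to [crop_structure()]: reads a CSV with columns
#' `structure_id, class` and attaches the hand labels to the structures.
#'
#' @param structures list of `exm_structure`s.
#' @param path CSV path.
#' @return the structures with `class_label` set from the file.
#' @export
ingest_manual_labels <- function(structures, path) {
  df <- utils::read.csv(path)
  if (!all(c("structure_id", "class") %in% names(df)))
    stop("manual label CSV needs columns structure_id, class", call. = FALSE)
  for (i in seq_along(structures)) {
    m <- match(structures[[i]]$id, df$structure_id)
    if (!is.na(m)) structures[[i]]$class_label <- df$class[m]
  }
  structures
}

#' Tabulate class frequencies
#'
#' @param structures list of classified `exm_structure`s.
#' @param classes class labels to tabulate (default 1..5).
#' @return data frame `class`, `n`; the counts sum to the number of
#'   structures.
#' @export
class_frequency_table <- function(structures, classes = 1:5) {
  labs <- vapply(structures, function(s) as.integer(s$class_label),
                 integer(1))
  data.frame(class = classes,
             n = vapply(classes, function(cl) sum(labs == cl), integer(1)))
}
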