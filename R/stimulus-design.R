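# Satellite category structure and CIELAB color/foil geometry.
#
# Two categories of four "satellite" objects; each satellite has four parts
# (head, tail, back, leg). Per category there are four shared parts (each on
# exactly three satellites) and four unique parts (each on exactly one), i.e.
# eight parts per category, sixteen in total. Part colors live on two circles
# of radius 14 in the L* = 60 plane of CIELAB space.

PART_TYPES <- c("head", "tail", "back", "leg")
CATEGORIES <- c("Alpha", "Gamma")
CODENAME_POOL <- c("Gavan", "Sorex", "Nodon", "Funda",
                   "Pellet", "Corda", "Bivet", "Zodon")

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(abs(seed) %% 2147483629))
  force(code)
}

#' Build the trained satellite set
#'
#' Constructs the eight-object, two-category satellite structure: per category,
#' four satellites with one part of each type, three of them shared with the
#' other category members and one unique. Each shared part occurs on exactly
#' three satellites of its category; each part type contributes one shared and
#' one unique part per category. Part identities, codenames, and the
#' unique-type rotation are randomized under the seed.
#'
#' @param seed Integer RNG seed; equal seeds give identical structures.
#' @return A tibble of class `satellite_set` with one row per satellite-part
#'   slot (32 rows): `satellite_id`, `category`, `class_name`, `code_name`,
#'   `novel`, `part_type`, `part_id`, `role`.
#' @export
#' @examples
#' set <- satellite_set(seed = 1)
#' dplyr::count(set, category, role)
satellite_set <- function(seed = 1L) {
  with_seed(seed, {
    part_ids <- sample(sprintf("p%02d", 1:16))
    codes <- sample(CODENAME_POOL)
    rows <- list()
    for (ci in seq_along(CATEGORIES)) {
      cat_name <- CATEGORIES[ci]
      ids <- part_ids[(ci - 1L) * 8L + 1:8]
      shared_of_type <- setNames(ids[1:4], PART_TYPES)
      unique_of_type <- setNames(ids[5:8], PART_TYPES)
      # rotate the unique type across the four satellites of the category
      unique_type <- sample(PART_TYPES)
      for (si in 1:4) {
        sat_id <- sprintf("sat%d", (ci - 1L) * 4L + si)
        code <- codes[(ci - 1L) * 4L + si]
        parts <- ifelse(PART_TYPES == unique_type[si],
                        unique_of_type[PART_TYPES],
                        shared_of_type[PART_TYPES])
        roles <- ifelse(PART_TYPES == unique_type[si], "unique", "shared")
        rows[[length(rows) + 1L]] <- tibble(
          satellite_id = sat_id, category = cat_name, class_name = cat_name,
          code_name = code, novel = FALSE,
          part_type = PART_TYPES, part_id = unname(parts), role = roles
        )
      }
    }
    out <- bind_rows(rows)
    class(out) <- c("satellite_set", class(out))
    attr(out, "seed") <- seed
    out
  })
}

#' Part inventory of a satellite set
#'
#' @param set A `satellite_set`.
#' @return Tibble with one row per part: `part_id`, `category`, `part_type`,
#'   `role`, `owners` (list-column of satellite ids), `n_owners`.
#' @export
part_table <- function(set) {
  set %>%
    group_by(.data$part_id, .data$category, .data$part_type, .data$role) %>%
    summarise(owners = list(unique(.data$satellite_id)), .groups = "drop") %>%
    mutate(n_owners = purrr::map_int(.data$owners, length)) %>%
    arrange(.data$category, .data$part_type, .data$role)
}

#' Build novel satellites for the post-learning test
#'
#' Creates eight novel satellites, four per trained category. Each replaces one
#' part type (rotated so each type is replaced once per category) with a
#' never-seen part, and fills the remaining three slots with that category's
#' shared parts of the other types. Novel satellites carry the class name but
#' no codename.
#'
#' @param base Trained `satellite_set`.
#' @param seed Integer RNG seed.
#' @return A `satellite_set` tibble of the 8 novel satellites (`novel = TRUE`;
#'   the novel part has `role = "novel"`).
#' @export
build_novel_set <- function(base, seed = 1L) {
  stopifnot(inherits(base, "satellite_set"), !any(base$novel))
  parts <- part_table(base)
  with_seed(seed, {
    novel_ids <- sample(sprintf("n%02d", 1:8))
    rows <- list()
    for (ci in seq_along(CATEGORIES)) {
      cat_name <- CATEGORIES[ci]
      shared <- parts %>% filter(.data$category == cat_name, .data$role == "shared")
      shared_of_type <- setNames(shared$part_id, shared$part_type)
      novel_type <- sample(PART_TYPES)
      for (si in 1:4) {
        idx <- (ci - 1L) * 4L + si
        parts_i <- ifelse(PART_TYPES == novel_type[si],
                          novel_ids[idx], shared_of_type[PART_TYPES])
        roles <- ifelse(PART_TYPES == novel_type[si], "novel", "shared")
        rows[[length(rows) + 1L]] <- tibble(
          satellite_id = sprintf("nov%d", idx), category = cat_name,
          class_name = cat_name, code_name = NA_character_, novel = TRUE,
          part_type = PART_TYPES, part_id = unname(parts_i), role = roles
        )
      }
    }
    out <- bind_rows(rows)
    class(out) <- c("satellite_set", class(out))
    out
  })
}

#' Equally spaced points on a circle in the (a*, b*) plane
#'
#' @param center Numeric length-2, circle center `(a, b)`.
#' @param radius Circle radius in CIELAB units (>= 0).
#' @param n_points Number of points (>= 1).
#' @param phase Angular offset of position 0, radians.
#' @return Tibble with columns `position` (0-based), `a`, `b`.
#' @export
#' @examples
#' cc <- color_circle(c(22, -25), 14, 8)
#' sqrt(diff(cc$a[1:2])^2 + diff(cc$b[1:2])^2)  # adjacent chord, 10.71
color_circle <- function(center, radius, n_points = 8L, phase = 0) {
  stopifnot(length(center) == 2L, radius >= 0)
  if (n_points < 1L) abort("n_points must be at least 1")
  ang <- phase + 2 * pi * (seq_len(n_points) - 1L) / n_points
  tibble(position = seq_len(n_points) - 1L,
         a = center[1] + radius * cos(ang),
         b = center[2] + radius * sin(ang))
}

# Shared-eligible circle positions per arrangement. Same-category same-type
# pairs (one shared + one unique part) must sit exactly two positions apart,
# so the two eligibility sets share parity blockwise: arrangement 1 uses
# {0,1,4,5} for shared parts, pairing (0,2),(1,3),(4,6),(5,7); arrangement 2
# swaps the shared and unique sets.
shared_positions <- function(arrangement_id) {
  stopifnot(arrangement_id %in% c(1L, 2L))
  if (arrangement_id == 1L) c(0L, 1L, 4L, 5L) else c(2L, 3L, 6L, 7L)
}

position_pairs <- function(arrangement_id) {
  sh <- shared_positions(arrangement_id)
  un <- (sh + 2L) %% 8L
  data.frame(shared = sh, unique = un)
}

#' Assign CIELAB colors to satellite parts
#'
#' Maps each of the 16 parts to one of 16 fixed color coordinates: eight
#' equally spaced points on each of two radius-14 circles in the L* = 60 CIELAB
#' plane (centers (22, -25) and (22, 25)). Which circle hosts which category is
#' randomized, as is the assignment of part types to circle positions, under
#' the constraints that same-category same-type parts sit exactly two
#' positions apart and that arrangement 2 equals arrangement 1 with the
#' shared- and unique-eligible position sets swapped.
#'
#' @param set Trained `satellite_set`.
#' @param arrangement_id 1 or 2.
#' @param seed Integer RNG seed.
#' @return Tibble of class `color_assignment`: `part_id`, `category`,
#'   `part_type`, `role`, `position`, `a`, `b`; attributes `centers`
#'   (per-category), `radius`, `lightness`, `arrangement_id`.
#' @export
assign_colors <- function(set, arrangement_id = 1L, seed = 1L) {
  stopifnot(inherits(set, "satellite_set"))
  parts <- part_table(set)
  circle_centers <- list(c(a = 22, b = -25), c(a = 22, b = 25))
  pairs <- position_pairs(arrangement_id)
  with_seed(seed, {
    circle_of <- sample(1:2) # category index -> circle index
    rows <- list()
    for (ci in seq_along(CATEGORIES)) {
      cat_name <- CATEGORIES[ci]
      center <- circle_centers[[circle_of[ci]]]
      circ <- color_circle(center, 14, 8L)
      type_pair <- sample(1:4) # part type -> position pair
      cat_parts <- parts %>% filter(.data$category == cat_name)
      for (ti in seq_along(PART_TYPES)) {
        pr <- pairs[type_pair[ti], ]
        for (r in c("shared", "unique")) {
          pos <- if (r == "shared") pr$shared else pr$unique
          pid <- cat_parts$part_id[cat_parts$part_type == PART_TYPES[ti] &
                                     cat_parts$role == r]
          rows[[length(rows) + 1L]] <- tibble(
            part_id = pid, category = cat_name, part_type = PART_TYPES[ti],
            role = r, position = pos,
            a = circ$a[circ$position == pos], b = circ$b[circ$position == pos]
          )
        }
      }
    }
    out <- bind_rows(rows) %>% arrange(.data$category, .data$position)
    class(out) <- c("color_assignment", class(out))
    attr(out, "centers") <- setNames(
      lapply(seq_along(CATEGORIES), function(i) circle_centers[[circle_of[i]]]),
      CATEGORIES)
    attr(out, "radius") <- 14
    attr(out, "lightness") <- 60
    attr(out, "arrangement_id") <- arrangement_id
    attr(out, "seed") <- seed
    out
  })
}

#' Category average color (circle center)
#'
#' The interpretable average color of a category is its circle center, which
#' equals the mean of the category's eight part coordinates.
#'
#' @param assignment A `color_assignment`.
#' @param category `"Alpha"` or `"Gamma"`.
#' @return Named numeric `(a, b)`.
#' @export
category_center <- function(assignment, category) {
  stopifnot(inherits(assignment, "color_assignment"))
  centers <- attr(assignment, "centers")
  if (!category %in% names(centers)) abort("unknown category")
  centers[[category]]
}

#' Build the 5AFC foil sets for part colors
#'
#' For each part, draws the line from its color coordinate to the category
#' circle center and its perpendicular through the coordinate. Foils sit at
#' `offset` CIELAB units from the target in the four directions, where
#' `offset` is exactly half the distance between adjacent part colors on the
#' circle (14 * sin(pi/8), printed as 5.35). The attract foil lies toward the
#' center, the repel foil away from it, and the two orthogonal foils are
#' mirror-symmetric about the attract-repel line.
#'
#' @param assignment A `color_assignment`.
#' @param part_ids Parts to build foils for; default all.
#' @return Tibble of class `foil_set` with one row per part x option
#'   (`target`, `attract`, `repel`, `orth1`, `orth2`): `part_id`, `category`,
#'   `part_type`, `role`, `option`, `a`, `b`. Attribute `offset`.
#' @export
make_foils <- function(assignment, part_ids = NULL) {
  stopifnot(inherits(assignment, "color_assignment"))
  if (is.null(part_ids)) part_ids <- assignment$part_id
  radius <- attr(assignment, "radius")
  offset <- radius * sin(pi / 8) # half the adjacent chord 2*r*sin(pi/8)
  rows <- purrr::map(part_ids, function(pid) {
    row <- assignment[assignment$part_id == pid, ]
    if (nrow(row) != 1L) abort(paste0("unknown part_id: ", pid))
    cen <- category_center(assignment, row$category)
    tgt <- c(row$a, row$b)
    d <- cen - tgt
    len <- sqrt(sum(d^2))
    if (len < 1e-9) abort("target coincides with category center; foil direction undefined")
    u <- d / len
    v <- c(-u[2], u[1])
    coords <- rbind(target = tgt, attract = tgt + offset * u,
                    repel = tgt - offset * u, orth1 = tgt + offset * v,
                    orth2 = tgt - offset * v)
    tibble(part_id = pid, category = row$category, part_type = row$part_type,
           role = row$role, option = rownames(coords),
           a = coords[, 1], b = coords[, 2])
  })
  out <- bind_rows(rows)
  class(out) <- c("foil_set", class(out))
  attr(out, "offset") <- offset
  out
}
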