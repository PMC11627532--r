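test_that("satellite set has the canonical category structure", {
  set <- fix_set
  expect_equal(nrow(set), 32L)
  expect_equal(length(unique(set$satellite_id)), 8L)
  counts <- dplyr::count(set, category, role)
  expect_setequal(counts$n[counts$role == "shared"], 12L) # 4 sats x 3 shared
  expect_setequal(counts$n[counts$role == "unique"], 4L)

  pt <- part_table(set)
  expect_equal(nrow(pt), 16L)
  expect_true(all(pt$n_owners[pt$role == "shared"] == 3L))
  expect_true(all(pt$n_owners[pt$role == "unique"] == 1L))
  # 2 parts of each type per category
  expect_true(all(dplyr::count(pt, category, part_type)$n == 2L))
  # every satellite: 3 shared + 1 unique, one part per type
  per_sat <- set %>% dplyr::group_by(satellite_id) %>%
    dplyr::summarise(n_shared = sum(role == "shared"),
                     n_unique = sum(role == "unique"),
                     n_types = dplyr::n_distinct(part_type))
  expect_true(all(per_sat$n_shared == 3L))
  expect_true(all(per_sat$n_unique == 1L))
  expect_true(all(per_sat$n_types == 4L))
})

test_that("satellite set construction is deterministic in the seed", {
  expect_identical(satellite_set(3), satellite_set(3))
  expect_false(identical(satellite_set(3)$part_id, satellite_set(4)$part_id))
})

test_that("novel satellites replace one part type with a never-seen part", {
  nov <- build_novel_set(fix_set, seed = 13)
  expect_equal(length(unique(nov$satellite_id)), 8L)
  expect_true(all(nov$novel))
  expect_true(all(is.na(nov$code_name)))
  expect_true(all(!is.na(nov$class_name)))
  trained_parts <- unique(fix_set$part_id)
  per_sat <- nov %>% dplyr::group_by(satellite_id, category) %>%
    dplyr::summarise(n_new = sum(!part_id %in% trained_parts),
                     overlap = sum(part_id %in% trained_parts), .groups = "drop")
  expect_true(all(per_sat$n_new == 1L))
  expect_true(all(per_sat$overlap >= 3L))
  # retained parts are the category's shared parts
  shared <- part_table(fix_set) %>% dplyr::filter(role == "shared")
  kept <- nov %>% dplyr::filter(role == "shared")
  expect_true(all(kept$part_id %in% shared$part_id))
})

test_that("color circle geometry matches the stated CIELAB layout", {
  cc <- color_circle(c(22, -25), 14, 8)
  chord <- sqrt(diff(cc$a[1:2])^2 + diff(cc$b[1:2])^2)
  expect_lt(abs(chord - 10.71), 0.01) # printed precision of the layout
  # all points on the circle to 1e-9
  expect_true(all(abs(sqrt((cc$a - 22)^2 + (cc$b + 25)^2) - 14) < 1e-9))
  # centroid identity
  expect_equal(c(mean(cc$a), mean(cc$b)), c(22, -25), tolerance = 1e-9)
  # degenerate radius
  cc0 <- color_circle(c(1, 2), 0, 5)
  expect_true(all(cc0$a == 1 & cc0$b == 2))
  expect_error(color_circle(c(0, 0), 1, 0), "n_points")
})

test_that("color assignment satisfies the position constraints", {
  asg <- fix_assignment
  expect_equal(nrow(asg), 16L)
  expect_equal(nrow(dplyr::distinct(asg, a, b)), 16L)
  for (cat in c("Alpha", "Gamma")) {
    cen <- category_center(asg, cat)
    sub <- asg[asg$category == cat, ]
    expect_true(all(abs(sqrt((sub$a - cen[1])^2 + (sub$b - cen[2])^2) - 14) < 1e-9))
    # center equals the mean of the 8 part coordinates
    expect_equal(unname(c(mean(sub$a), mean(sub$b))), unname(cen), tolerance = 1e-9)
    # same-type pairs exactly two positions apart
    for (ty in unique(sub$part_type)) {
      pos <- sort(sub$position[sub$part_type == ty])
      d <- min((pos[2] - pos[1]) %% 8, (pos[1] - pos[2]) %% 8)
      expect_equal(d, 2L)
    }
  }
})

test_that("arrangement 2 swaps the shared and unique coordinate sets", {
  a1 <- assign_colors(fix_set, 1, seed = 12)
  a2 <- assign_colors(fix_set, 2, seed = 12)
  coord_set <- function(a, r) {
    sub <- a[a$role == r, ]
    sub <- sub[order(sub$a, sub$b), ]
    round(cbind(sub$a, sub$b), 9)
  }
  expect_equal(coord_set(a1, "shared"), coord_set(a2, "unique"))
  expect_equal(coord_set(a1, "unique"), coord_set(a2, "shared"))
  # swap applied twice is the identity on position sets
  expect_identical(catwarp:::shared_positions(1),
                   sort((catwarp:::shared_positions(2) + 2L) %% 8L))
})

test_that("foil geometry: offsets, attract/repel distances, orthogonal symmetry", {
  foils <- make_foils(fix_assignment)
  offset <- attr(foils, "offset")
  expect_equal(offset, 14 * sin(pi / 8), tolerance = 1e-12)
  expect_lt(abs(offset - 5.35), 0.01)
  wide <- foils %>% tidyr::pivot_wider(names_from = option,
                                       values_from = c(a, b))
  for (i in seq_len(nrow(wide))) {
    w <- wide[i, ]
    cen <- category_center(fix_assignment, w$category)
    tgt <- c(w$a_target, w$b_target)
    d_to <- function(p) sqrt(sum((p - tgt)^2))
    d_cen <- function(p) sqrt(sum((p - cen)^2))
    # all four foils at exactly `offset` from the target
    for (opt in c("attract", "repel", "orth1", "orth2")) {
      p <- c(w[[paste0("a_", opt)]], w[[paste0("b_", opt)]])
      expect_lt(abs(d_to(p) - offset), 1e-9)
    }
    # independent vector-arithmetic oracle along the center line
    expect_lt(abs(d_cen(c(w$a_attract, w$b_attract)) - (14 - offset)), 1e-9)
    expect_lt(abs(d_cen(c(w$a_repel, w$b_repel)) - (14 + offset)), 1e-9)
    expect_lt(abs(d_cen(c(w$a_orth1, w$b_orth1)) -
                    d_cen(c(w$a_orth2, w$b_orth2))), 1e-9)
  }
})

test_that("foil construction rejects a target at the category center", {
  asg <- fix_assignment
  bad <- asg
  cen <- category_center(asg, bad$category[1])
  bad$a[1] <- cen[1]
  bad$b[1] <- cen[2]
  expect_error(make_foils(bad, bad$part_id[1]), "center")
})
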