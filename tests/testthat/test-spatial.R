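test_that("edge travel minutes follow length / speed * 60", {
  expect_equal(edge_travel_minutes(60, "tertiary"), 60)
  expect_equal(edge_travel_minutes(60, "tracks"), 180)
  expect_equal(edge_travel_minutes(0.5 * 120, "primary"), 30)
  expect_equal(edge_travel_minutes(10, "residential"), 15)
  expect_error(edge_travel_minutes(0, "primary"), "positive")
  expect_error(edge_travel_minutes(-2, "tracks"), "positive")
  expect_error(edge_travel_minutes(5, "footpath"), "unknown road class")
  expect_error(edge_travel_minutes(5, "primary", c(primary = 0)), "positive")
})

test_that("graph construction merges endpoints and collapses parallel edges", {
  r <- data.frame(segment_id = c("s1", "s2"),
                  road_class = c("primary", "primary"),
                  stringsAsFactors = FALSE)
  r$geometry <- list(rbind(c(0, 0), c(1, 0)), rbind(c(1, 0), c(2, 0)))
  g <- build_road_graph(r)
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)

  # duplicated pair: cheaper (faster class) survives
  r2 <- data.frame(segment_id = c("a", "b"),
                   road_class = c("tracks", "primary"),
                   stringsAsFactors = FALSE)
  r2$geometry <- list(rbind(c(0, 0), c(10, 0)), rbind(c(0, 0), c(10, 0)))
  g2 <- build_road_graph(r2)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$road_class, "primary")
  expect_equal(g2$edges$minutes, 10 / 120 * 60)

  # 4-edge fixture: weights equal the arithmetic by hand
  g4 <- build_road_graph(line_roads())
  expect_equal(sort(g4$edges$minutes),
               sort(c(10 / 120, 20 / 80, 30 / 60, 40 / 20) * 60))
})

test_that("lake barriers remove crossing edges and force longer routes", {
  # two-path network: short top path A-B-C, long bottom path A-D-C
  r <- data.frame(segment_id = paste0("s", 1:4),
                  road_class = "tertiary", stringsAsFactors = FALSE)
  r$geometry <- list(
    rbind(c(0, 0), c(10, 5)), rbind(c(10, 5), c(20, 0)),   # top
    rbind(c(0, 0), c(10, -20)), rbind(c(10, -20), c(20, 0)) # bottom
  )
  g <- build_road_graph(r)
  fac <- data.frame(facility_id = "F", x = 0, y = 0)
  gs <- snap_facilities(g, fac)
  t_before <- travel_time_surface(gs)
  nC <- gs$nodes$node_id[gs$nodes$x == 20 & gs$nodes$y == 0]
  m_before <- t_before$nodes$minutes[t_before$nodes$node_id == nC]

  lake <- rbind(c(5, 1), c(15, 1), c(15, 8), c(5, 8))  # covers the top path
  gb <- snap_facilities(apply_barriers(g, lake = list(lake)), fac)
  expect_lt(nrow(gb$edges), nrow(g$edges))
  t_after <- travel_time_surface(gb)
  m_after <- t_after$nodes$minutes[t_after$nodes$node_id == nC]
  expect_gt(m_after, m_before)

  # non-intersecting lake: identity
  far <- rbind(c(100, 100), c(110, 100), c(110, 110), c(100, 110))
  expect_equal(apply_barriers(g, list(far))$edges, g$edges)

  # lake on a cut edge: downstream nodes become unreachable
  line <- build_road_graph(line_roads())
  cut <- rbind(c(12, -1), c(18, -1), c(18, 1), c(12, 1))
  gl <- snap_facilities(apply_barriers(line, list(cut)),
                        data.frame(facility_id = "F", x = 0, y = 0))
  tl <- travel_time_surface(gl)
  right_nodes <- tl$nodes$minutes[tl$nodes$x > 18]
  expect_true(all(!is.finite(right_nodes)))
})

test_that("facility snapping respects the 15 km tolerance and splits edges", {
  g <- build_road_graph(line_roads())
  on_edge <- data.frame(facility_id = "F1", x = 15, y = 0)
  gs <- snap_facilities(g, on_edge)
  expect_equal(gs$facilities$snap_km, 0)
  expect_equal(nrow(gs$edges), nrow(g$edges) + 1)  # split edge

  off <- data.frame(facility_id = "F2", x = 50, y = 20)
  go <- snap_facilities(g, off)
  expect_equal(nrow(go$facilities), 0)
  expect_equal(go$unlocated$facility_id, "F2")

  near <- data.frame(facility_id = "F3", x = 50, y = 10)
  gn <- snap_facilities(g, near)
  expect_equal(gn$facilities$snap_km, 10)

  # three facilities, one off-network: two located, one reported
  three <- data.frame(facility_id = c("A", "B", "C"),
                      x = c(5, 60, 0), y = c(0, 30, -14))
  g3 <- snap_facilities(g, three)
  expect_equal(nrow(g3$facilities), 2)
  expect_equal(g3$unlocated$facility_id, "B")
})

test_that("travel-time surface equals the exhaustive-path oracle", {
  # 5-node path with known weights
  g <- snap_facilities(build_road_graph(line_roads()),
                       data.frame(facility_id = "F", x = 0, y = 0))
  s <- travel_time_surface(g)
  w <- c(10 / 120, 20 / 80, 30 / 60, 40 / 20) * 60
  exp_min <- c(0, cumsum(w))
  got <- s$nodes$minutes[order(s$nodes$x)]
  expect_equal(got, exp_min, tolerance = 1e-10)
  # facility node: zero minutes, band 1
  f_node <- s$nodes[s$nodes$node_id == g$facilities$node_id, ]
  expect_equal(f_node$minutes, 0)
  expect_equal(f_node$band, 1L)

  # random small graphs vs the brute-force enumeration oracle
  set.seed(123)
  for (rep in 1:12) {
    nr <- random_small_roads(sample(4:8, 1))
    gg <- build_road_graph(nr)
    fnode <- gg$nodes$node_id[sample.int(nrow(gg$nodes), 1)]
    fac <- data.frame(facility_id = "F",
                      x = gg$nodes$x[gg$nodes$node_id == fnode],
                      y = gg$nodes$y[gg$nodes$node_id == fnode])
    gf <- snap_facilities(gg, fac)
    ss <- travel_time_surface(gf)
    oracle <- brute_force_shortest(
      gf$nodes$node_id,
      data.frame(from = gf$edges$from, to = gf$edges$to,
                 w = gf$edges$minutes, stringsAsFactors = FALSE),
      gf$facilities$node_id)
    got <- setNames(ss$nodes$minutes, ss$nodes$node_id)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-9)
  }
  expect_error(travel_time_surface(build_road_graph(line_roads())),
               "no located facilities")
})

test_that("band intervals partition (0, 240] with boundary rules as stated", {
  breaks <- c(30, 45, 60, 90, 180, 240)
  expect_equal(assign_band(c(0, 30, 30.0001, 45, 60.5, 90, 179, 240)),
               c(1L, 1L, 2L, 2L, 4L, 4L, 5L, 6L))
  expect_true(is.na(assign_band(241)))
  expect_true(is.na(assign_band(Inf)))
  # every value in (0, 240] lands in exactly one band
  x <- seq(0.001, 240, length.out = 997)
  b <- assign_band(x, breaks)
  expect_false(anyNA(b))
  for (k in seq_along(breaks)) {
    lo <- if (k == 1) 0 else breaks[k - 1]
    in_band <- x[b == k]
    expect_true(all(in_band > lo & in_band <= breaks[k]))
  }
})

test_that("adding facilities never increases, removing barriers never decreases", {
  set.seed(321)
  nr <- random_small_roads(8, n_extra = 4)
  g <- build_road_graph(nr)
  f1 <- data.frame(facility_id = "F1", x = g$nodes$x[1], y = g$nodes$y[1])
  f2 <- data.frame(facility_id = c("F1", "F2"),
                   x = c(g$nodes$x[1], g$nodes$x[6]),
                   y = c(g$nodes$y[1], g$nodes$y[6]))
  t1 <- travel_time_surface(snap_facilities(g, f1))$nodes
  t2 <- travel_time_surface(snap_facilities(g, f2))$nodes
  m1 <- setNames(t1$minutes, t1$node_id)
  m2 <- setNames(t2$minutes, t2$node_id)
  common <- intersect(names(m1), names(m2))
  expect_true(all(m2[common] <= m1[common] + 1e-9))

  # a barrier can only lengthen (or sever) routes
  lake <- rbind(c(25, -6), c(45, -6), c(45, 6), c(25, 6))
  gb <- apply_barriers(g, list(lake))
  tb <- travel_time_surface(snap_facilities(gb, f1))$nodes
  mb <- setNames(tb$minutes, tb$node_id)
  common <- intersect(names(m1), names(mb))
  expect_true(all(mb[common] >= m1[common] - 1e-9))
})

test_that("district access report gives band shares summing to one", {
  g <- snap_facilities(build_road_graph(line_roads()),
                       data.frame(facility_id = "F", x = 0, y = 0))
  s <- travel_time_surface(g)
  pts <- data.frame(district_id = rep(c("D1", "D2"), each = 2),
                    x = c(0, 10, 99, 100), y = 0)
  rep_ <- district_access_report(s, pts)
  shares <- rowSums(rep_[, grep("^band_|unreachable", names(rep_))])
  expect_equal(shares, rep(1, 2), tolerance = 1e-9)
  # women at the facility node: all in band 1
  at_fac <- district_access_report(
    s, data.frame(district_id = "D", x = c(0, 0), y = c(0, 0)))
  expect_equal(at_fac$band_1, 1)
  expect_equal(at_fac$median_minutes, 0)

  # a remote district beyond the last band is flagged
  long <- data.frame(segment_id = "L", road_class = "tracks",
                     stringsAsFactors = FALSE)
  long$geometry <- list(rbind(c(0, 0), c(90, 0)))  # 270 min of track
  gl <- snap_facilities(build_road_graph(long),
                        data.frame(facility_id = "F", x = 0, y = 0))
  sl <- travel_time_surface(gl)
  remote <- district_access_report(
    sl, data.frame(district_id = "R", x = 90, y = 0))
  expect_true(remote$flag_over_max)
})
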