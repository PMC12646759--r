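# Small hand-built fixtures used across test files.

# Two-month, two-bird, three-plant site with a filmed-but-unvisited plant.
toyTable <- function() {
    MonthlyVisitTable(data.frame(
        site = "s1",
        month = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
        plant = c("P1", "P1", "P2", "P3", "P1", "P2", "P3"),
        bird = c("H1", "H2", "H1", NA, "H1", "H2", "H2"),
        visits = c(6L, 2L, 3L, 0L, 2L, 4L, 5L),
        recording_hours = c(3, 3, 2, 10, 1, 4, 2)))
}

# Asymmetric-effort fixture for allocation calibration: one bird, 10 visits
# in one month, two plants filmed 3 h and 1 h.
allocTable <- function() {
    MonthlyVisitTable(data.frame(
        site = "s1", month = 1L,
        plant = c("P1", "P2"), bird = c("H1", "H1"),
        visits = c(5L, 5L), recording_hours = c(3, 1)))
}

# Planted block-diagonal visit table: two guild-matched modules, each bird
# visiting only its own module's plants, equal recording effort.
plantedModuleTable <- function() {
    rec <- rbind(
        expand.grid(bird = c("H1", "H2"), plant = c("P1", "P2"),
                    stringsAsFactors = FALSE),
        expand.grid(bird = c("H3", "H4"), plant = c("P3", "P4"),
                    stringsAsFactors = FALSE))
    MonthlyVisitTable(data.frame(
        site = "s1", month = 1L, plant = rec$plant, bird = rec$bird,
        visits = 5L, recording_hours = 6))
}
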