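# Random normalized FAME profiles over a fixed acid panel, for property tests.
ACID_PANEL <- c("C14:0", "C15:0", "C16:0", "C18:0", "C16:1", "C18:1",
                "C16:2", "C18:2", "C18:3", "C20:4", "C20:5", "C22:6")

random_profile <- function(n_acids = sample(3:length(ACID_PANEL), 1)) {
  acids <- sample(ACID_PANEL, n_acids)
  fame_profile(stats::setNames(stats::runif(n_acids, 0.01, 10), acids))
}

# Run-mean response vector in design run order from the packaged fixture.
fixture_run_means <- function(strain, what = c("cfu", "od")) {
  what <- match.arg(what)
  d <- load_study_fixtures()$design_responses
  d <- d[d$strain == strain, ]
  d[[what]][order(d$run)]
}
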