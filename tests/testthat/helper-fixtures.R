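# Shared fixtures: all built in code at test time.

# a deterministic latent profile with controllable traits
test_profile <- function(group = "TR", kEffort = 0.204, kMoney = 0.02,
                         kFood = 0.25, kExercise = 0.17,
                         trainingGain = 0.09, detrainFraction = 0.8,
                         conditioningDeltaM = if (group == "COTR") 0.2 else 0,
                         choiceNoise = 0, ratingNoiseSD = 0,
                         hrPerSpeed0 = 22, age = 25, baselineHR = 115) {
  data.frame(id = "P001", group = group, age = age,
             baselineHR = baselineHR, hrMax = 220 - age,
             hrPerSpeed0 = hrPerSpeed0, trainingGain = trainingGain,
             detrainFraction = detrainFraction, kMoney = kMoney,
             kFood = kFood, kExercise = kExercise, kEffort = kEffort,
             conditioningDeltaM = conditioningDeltaM,
             choiceNoise = choiceNoise, ratingNoiseSD = ratingNoiseSD,
             stringsAsFactors = FALSE)
}

# noise-free hyperbolic responder: prefers immediate iff its face value
# beats the discounted delayed value
hyperbolic_responder <- function(k) {
  function(immediateAmount, delayedAmount, delayDays) {
    if (immediateAmount > delayedAmount / (1 + k * delayDays)) "immediate"
    else "delayed"
  }
}

# independent dense grid-search oracle for a single-k least-squares
# objective; deliberately brute force, no reuse of package internals
grid_oracle <- function(ss, grid = c(0, exp(seq(log(1e-8), log(100),
                                                length.out = 20001)))) {
  grid[which.min(vapply(grid, ss, numeric(1)))]
}

# exact sign-test p-value by full enumeration of all 2^n sign patterns
enumerate_sign_p <- function(diffs) {
  nz <- diffs[diffs != 0]
  n <- length(nz)
  if (n == 0) return(1)
  x <- sum(nz > 0)
  npos <- vapply(0:(2^n - 1), function(m) {
    sum(bitwAnd(m, 2^(0:(n - 1))) > 0)
  }, numeric(1))
  mean(abs(npos - n / 2) >= abs(x - n / 2))
}
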