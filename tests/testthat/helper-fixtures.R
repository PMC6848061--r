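# Small geometries and foci used across tests.

smallGeometry <- function(nFrames = 60L, height = 40L, width = 56L,
                          stimOnsetFrame = 20L) {
  AcquisitionGeometry(nFrames = nFrames, height = height, width = width,
                      stimOnsetFrame = stimOnsetFrame)
}

smallFocus <- function(amplitude = 0.0089, centerRow = 20, centerCol = 28,
                       sigma = 6, onsetDelay = 30, label = "S1") {
  ResponseFocus(label, centerRow, centerCol, sigma = sigma,
                amplitude = amplitude, onsetDelay = onsetDelay)
}

noiselessParams <- function(geometry = smallGeometry(), foci = list(smallFocus()),
                            seed = 1L, nTrials = 1L) {
  SimParams(geometry, foci, baselineF0 = 1000, bleachTau = Inf, noiseSd = 0,
            trialJitterCv = 0, nTrials = nTrials, seed = seed)
}

# Constant-valued DffMovie helper.
constantDff <- function(value, geometry = smallGeometry()) {
  new("DffMovie",
      frames = array(value, c(geometry@nFrames, geometry@height, geometry@width)),
      geometry = geometry, provenance = "dff")
}

# The six group comparisons whose printed significance statement is
# reproducible from the rounded printed summaries alone.
robustComparisons <- function() {
  data.frame(
    stimulation = c("whisker_pad", "molar_pulp", "molar_pulp", "molar_pulp",
                    "mentum_skin", "mentum_skin"),
    region = c("S1_S2", "S1", "S2_IOR", "S2_IOR", "S1", "S1"),
    group_a = c("sham", "sham", "sham", "sham", "sham", "plion"),
    group_b = c("plion", "plion", "plion", "plion_minocycline", "plion",
                "plion_minocycline"),
    printed = c("<0.016", "<0.016", "<0.001", "0.03", "<0.016", "<0.016"),
    stringsAsFactors = FALSE
  )
}
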