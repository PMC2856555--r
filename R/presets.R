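# Frozen tissue-panel presets.
#
# target_index is the instability index each tissue should measure under the
# default rendering (stutter 0.15, amplification bias 0.01, 20% threshold),
# on the scale of observed knock-in mouse tissues (striatum most unstable,
# testis/heart slightly negative).  expansion_rate / contraction_mass /
# tail_shape were fixed once by root finding on the full render-and-quantify
# pipeline so the measured indices land on the targets (to within the
# pipeline's discrete threshold steps); they are data, not knobs.
# Contraction fraction: 0.15 baseline, 0.05 in the two strongly expanding
# tissues, larger in stable tissues whose traces read negative.
.presetTable <- data.frame(
    tissue = c("tail", "cortex", "striatum", "cerebellum", "liver", "heart",
               "lung", "stomach", "spleen", "skin", "kidney", "ovary",
               "testis", "hippocampus", "pancreas", "large_intestine",
               "small_intestine"),
    target_index = c(0.00, 0.98, 6.37, 0.96, 5.63, -1.01, -0.82, 0.82,
                     -0.26, -0.61, 1.17, -0.47, -1.03, 0.07, 0.09, -0.67,
                     -0.29),
    expansion_rate = c(0.00000000, 1.47532697, 12.17473459, 1.30100461,
                       10.64067917, 0.00000000, 0.00000000, 1.17120187,
                       0.00000000, 0.00000000, 1.51373044, 0.00000000,
                       0.00000000, 0.49486295, 0.52628822, 0.00000000,
                       0.00000000),
    contraction_mass = c(0.00000000, 0.15000000, 0.05000000, 0.15000000,
                         0.05000000, 0.69648864, 0.54360629, 0.15000000,
                         0.22887638, 0.37177091, 0.15000000, 0.28598013,
                         0.71244101, 0.15000000, 0.15000000, 0.42117757,
                         0.27620672),
    tail_shape = c(0.30000000, 0.43741285, 0.92361230, 0.36203147,
                   0.91259956, 0.30000000, 0.30000000, 0.30000000,
                   0.30000000, 0.30000000, 0.45168573, 0.30000000,
                   0.30000000, 0.30000000, 0.30000000, 0.30000000,
                   0.30000000),
    stringsAsFactors = FALSE)
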