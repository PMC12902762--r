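# Default three-tier screening battery: five symptom scales, 56 distinct items.
# Tier 1 is the distress gateway; Tier 2 short forms are subsets of the Tier 3
# full scales, so their responses carry over into the full-scale scores.
# All cutoffs are "positive iff score >= cutoff".
name: i-TAP default
scales:
  - scale_id: rhs13
    tier: 1
    disorder: distress
    cutoff: 11
    items: {prefix: rhs13, count: 13, min: 0, max: 4}
  - scale_id: phq9
    tier: 3
    disorder: depression
    cutoff: 10
    items: {prefix: phq9, count: 9, min: 0, max: 3}
  - scale_id: gad7
    tier: 3
    disorder: anxiety
    cutoff: 10
    items: {prefix: gad7, count: 7, min: 0, max: 3}
  - scale_id: pcl5
    tier: 3
    disorder: ptsd
    cutoff: 32
    items: {prefix: pcl5, count: 20, min: 0, max: 4}
  - scale_id: isi7
    tier: 3
    disorder: insomnia
    cutoff: 11
    items: {prefix: isi7, count: 7, min: 0, max: 4}
short_forms:
  - scale_id: phq2
    parent: phq9
    cutoff: 2
    items: [phq9_1, phq9_2]
  - scale_id: gad2
    parent: gad7
    cutoff: 2
    items: [gad7_1, gad7_2]
  # 4-item abbreviated PCL-5; item membership is configuration, not doctrine
  - scale_id: pcl5sf
    parent: pcl5
    cutoff: 5
    items: [pcl5_1, pcl5_4, pcl5_7, pcl5_10]
  - scale_id: isi_gate
    parent: isi7
    cutoff: 2
    items: [isi7_7]
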