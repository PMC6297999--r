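# Species threshold presets.
#
# Threshold bands are the flax-calibrated values for all species; only the
# area-range filters differ (scaled to typical seed and halo sizes, in
# mm^2). Recalibrate bands for a new imaging setup with the automatic
# threshold suggester and overlay inspection (see the package vignette).

linum:
  mucilage: {h: [172, 255], s: [24, 255], v: [85, 255]}
  seed:     {h: [0, 255],   s: [0, 255],  v: [0, 70]}
  mucilage_area: [18, 315]
  seed_area: [0.5, 50]

arabidopsis:
  mucilage: {h: [172, 255], s: [24, 255], v: [85, 255]}
  seed:     {h: [0, 255],   s: [0, 255],  v: [0, 70]}
  mucilage_area: [0.5, 30]
  seed_area: [0.02, 2]

camelina:
  mucilage: {h: [172, 255], s: [24, 255], v: [85, 255]}
  seed:     {h: [0, 255],   s: [0, 255],  v: [0, 70]}
  mucilage_area: [5, 150]
  seed_area: [0.2, 20]

plantago:
  mucilage: {h: [172, 255], s: [24, 255], v: [85, 255]}
  seed:     {h: [0, 255],   s: [0, 255],  v: [0, 70]}
  mucilage_area: [5, 150]
  seed_area: [0.2, 20]

capsella:
  mucilage: {h: [172, 255], s: [24, 255], v: [85, 255]}
  seed:     {h: [0, 255],   s: [0, 255],  v: [0, 70]}
  mucilage_area: [2, 80]
  seed_area: [0.1, 10]
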