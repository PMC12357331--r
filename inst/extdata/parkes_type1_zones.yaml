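# Parkes consensus error grid, Type 1 diabetes variant.
#
# Published consensus breakpoint coordinates (Pfuetzner and colleagues'
# tabulation of the Parkes grid), reference glucose on x, meter glucose on
# y, both in mg/dL over [0, 550]. Zones are cumulative nested polygons:
# polygon "A" is zone A itself, polygon "B" is "risk B or better", ...,
# "E" covers the whole domain. Classification assigns the first (safest)
# polygon containing a point, so shared boundaries resolve to the
# lower-risk zone. Override by passing your own file of the same shape to
# load_zone_polygons().
grid_name: "Parkes consensus error grid (Type 1 diabetes)"
domain: [0, 550]
zones:
  - zone: A
    vertices: [[0, 0], [0, 50], [30, 50], [140, 170], [280, 380], [430, 550],
               [550, 550], [550, 450], [385, 300], [170, 145], [50, 30], [50, 0]]
  - zone: B
    vertices: [[0, 0], [0, 60], [30, 60], [50, 80], [70, 110], [260, 550],
               [550, 550], [550, 250], [260, 130], [120, 30], [120, 0]]
  - zone: C
    vertices: [[0, 0], [0, 100], [25, 100], [50, 125], [80, 215], [125, 550],
               [550, 550], [550, 150], [250, 40], [250, 0]]
  - zone: D
    vertices: [[0, 0], [0, 150], [35, 155], [50, 550], [550, 550], [550, 0]]
  - zone: E
    vertices: [[0, 0], [0, 550], [550, 550], [550, 0]]
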