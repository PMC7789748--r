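charset: '0123456789.-%/: ABCDEFGHIJKLMNOPQRSTUVWXYZ'
layouts:
- type_id: rnfl_unilateral
  header_title: RNFL ANALYSIS SINGLE EXAM
  header_box:
  - 12
  - 10
  - 470
  - 40
  page_size:
  - 640
  - 480
  version_range: 1.7.0.0-1.10.4.0
  fields:
  - name: patient_id
    kind: text
    box:
    - 90
    - 52
    - 206
    - 78
    unit: ''
    pattern: ^[0-9]{4,12}$
    charset: 0123456789
  - name: visit_date
    kind: date
    box:
    - 300
    - 52
    - 432
    - 78
    unit: ''
    pattern: ^[0-9]{4}-[0-9]{2}-[0-9]{2}$
    charset: 0123456789-
  - name: laterality
    kind: text
    box:
    - 520
    - 52
    - 624
    - 78
    unit: ''
    pattern: ^(RIGHT|LEFT)$
    charset: RIGHTLEF
  - name: global_rnfl_thickness
    kind: numeric
    box:
    - 150
    - 120
    - 260
    - 146
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: superior_rnfl_thickness
    kind: numeric
    box:
    - 150
    - 160
    - 260
    - 186
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: inferior_rnfl_thickness
    kind: numeric
    box:
    - 150
    - 200
    - 260
    - 226
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
- type_id: rnfl_bilateral
  header_title: RNFL ANALYSIS OU REPORT
  header_box:
  - 12
  - 10
  - 470
  - 40
  page_size:
  - 640
  - 480
  version_range: 1.7.0.0-1.10.4.0
  fields:
  - name: patient_id
    kind: text
    box:
    - 90
    - 52
    - 206
    - 78
    unit: ''
    pattern: ^[0-9]{4,12}$
    charset: 0123456789
  - name: visit_date
    kind: date
    box:
    - 300
    - 52
    - 432
    - 78
    unit: ''
    pattern: ^[0-9]{4}-[0-9]{2}-[0-9]{2}$
    charset: 0123456789-
  - name: right_global_rnfl_thickness
    kind: numeric
    box:
    - 150
    - 120
    - 260
    - 146
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: right_superior_rnfl_thickness
    kind: numeric
    box:
    - 150
    - 160
    - 260
    - 186
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: right_inferior_rnfl_thickness
    kind: numeric
    box:
    - 150
    - 200
    - 260
    - 226
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: left_global_rnfl_thickness
    kind: numeric
    box:
    - 400
    - 120
    - 510
    - 146
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: left_superior_rnfl_thickness
    kind: numeric
    box:
    - 400
    - 160
    - 510
    - 186
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: left_inferior_rnfl_thickness
    kind: numeric
    box:
    - 400
    - 200
    - 510
    - 226
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
- type_id: macula_current
  header_title: MACULAR THICKNESS SINGLE EXAM
  header_box:
  - 12
  - 10
  - 470
  - 40
  page_size:
  - 640
  - 480
  version_range: 1.7.0.0-1.10.4.0
  fields:
  - name: patient_id
    kind: text
    box:
    - 90
    - 52
    - 206
    - 78
    unit: ''
    pattern: ^[0-9]{4,12}$
    charset: 0123456789
  - name: visit_date
    kind: date
    box:
    - 300
    - 52
    - 432
    - 78
    unit: ''
    pattern: ^[0-9]{4}-[0-9]{2}-[0-9]{2}$
    charset: 0123456789-
  - name: laterality
    kind: text
    box:
    - 520
    - 52
    - 624
    - 78
    unit: ''
    pattern: ^(RIGHT|LEFT)$
    charset: RIGHTLEF
  - name: total_macular_volume
    kind: numeric
    box:
    - 150
    - 120
    - 260
    - 146
    unit: mm³
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: central_macular_thickness
    kind: numeric
    box:
    - 150
    - 160
    - 260
    - 186
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: macula_scan
    kind: tomogram
    box:
    - 60
    - 240
    - 580
    - 420
    unit: ''
- type_id: macula_prev_current
  header_title: MACULAR THICKNESS CHANGE REPORT
  header_box:
  - 12
  - 10
  - 470
  - 40
  page_size:
  - 640
  - 480
  version_range: 1.7.0.0-1.10.4.0
  fields:
  - name: patient_id
    kind: text
    box:
    - 90
    - 52
    - 206
    - 78
    unit: ''
    pattern: ^[0-9]{4,12}$
    charset: 0123456789
  - name: visit_date
    kind: date
    box:
    - 300
    - 52
    - 432
    - 78
    unit: ''
    pattern: ^[0-9]{4}-[0-9]{2}-[0-9]{2}$
    charset: 0123456789-
  - name: laterality
    kind: text
    box:
    - 520
    - 52
    - 624
    - 78
    unit: ''
    pattern: ^(RIGHT|LEFT)$
    charset: RIGHTLEF
  - name: prev_total_macular_volume
    kind: numeric
    box:
    - 150
    - 120
    - 260
    - 146
    unit: mm³
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: prev_central_macular_thickness
    kind: numeric
    box:
    - 150
    - 160
    - 260
    - 186
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: total_macular_volume
    kind: numeric
    box:
    - 400
    - 120
    - 510
    - 146
    unit: mm³
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: central_macular_thickness
    kind: numeric
    box:
    - 400
    - 160
    - 510
    - 186
    unit: µm
    pattern: ^-?[0-9]+(\.[0-9]+)?$
    charset: 0123456789.-
  - name: macula_scan
    kind: tomogram
    box:
    - 60
    - 240
    - 580
    - 420
    unit: ''
- type_id: macula_scan_current
  header_title: MACULA SCAN SINGLE EXAM
  header_box:
  - 12
  - 10
  - 470
  - 40
  page_size:
  - 640
  - 480
  version_range: 1.7.0.0-1.10.4.0
  fields:
  - name: horizontal_scan
    kind: tomogram
    box:
    - 60
    - 80
    - 580
    - 250
    unit: ''
  - name: vertical_scan
    kind: tomogram
    box:
    - 60
    - 270
    - 580
    - 440
    unit: ''
- type_id: macula_scan_prev_current
  header_title: MACULA SCAN CHANGE REPORT
  header_box:
  - 12
  - 10
  - 470
  - 40
  page_size:
  - 640
  - 480
  version_range: 1.7.0.0-1.10.4.0
  fields:
  - name: prev_horizontal_scan
    kind: tomogram
    box:
    - 40
    - 80
    - 300
    - 250
    unit: ''
  - name: horizontal_scan
    kind: tomogram
    box:
    - 340
    - 80
    - 600
    - 250
    unit: ''
  - name: prev_vertical_scan
    kind: tomogram
    box:
    - 40
    - 270
    - 300
    - 440
    unit: ''
  - name: vertical_scan
    kind: tomogram
    box:
    - 340
    - 270
    - 600
    - 440
    unit: ''
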