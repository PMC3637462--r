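onset_base: 0.008
onset_slope: 0.04
low_to_inthigh: 0.035
inthigh_to_crc: 0.03
progression:
- 0.4
- 0.45
- 0.48
presentation:
- 0.1
- 0.28
- 0.5
- 0.9
fatality:
- 0.01
- 0.04
- 0.15
- 0.45
remission:
- 0.2
- 0.15
- 0.08
- 0.02
other_cause_mortality:
  '30': 0.000473995288448
  '31': 0.000519671760086
  '32': 0.000569749836787
  '33': 0.00062465367844
  '34': 0.000684848319025
  '35': 0.00075084360544
  '36': 0.000823198515889
  '37': 0.00090252589441
  '38': 0.000989497641648
  '39': 0.001084850405835
  '40': 0.001189391822177
  '41': 0.001304007353506
  '42': 0.001429667790118
  '43': 0.001567437472348
  '44': 0.001718483305493
  '45': 0.001884084643476
  '46': 0.00206564412493
  '47': 0.002264699553511
  '48': 0.002482936923052
  '49': 0.002722204697879
  '50': 0.002984529469258
  '51': 0.003272133120558
  '52': 0.003587451646545
  '53': 0.003933155786188
  '54': 0.00431217364374
  '55': 0.004727715489701
  '56': 0.005183300951715
  '57': 0.005682788825718
  '58': 0.006230409759831
  '59': 0.006830802087828
  '60': 0.007489051115691
  '61': 0.008210732194009
  '62': 0.009001957941037
  '63': 0.009869430016404
  '64': 0.010820495883974
  '65': 0.01186321104466
  '66': 0.013006407266286
  '67': 0.014259767388412
  '68': 0.01563390733571
  '69': 0.017140466034544
  '70': 0.018792203994345
  '71': 0.020603111388766
  '72': 0.022588526552056
  '73': 0.024765265894312
  '74': 0.027151766336002
  '75': 0.029768241468151
  '76': 0.032636852760888
  '77': 0.035781897270469
  '78': 0.039230013434652
  '79': 0.04301040669951
  '80': 0.047155096888732
  '81': 0.051699189410618
  '82': 0.056681172599895
  '83': 0.062143243712815
  '84': 0.068131666336726
  '85': 0.074697162241334
  '86': 0.081895340990662
  '87': 0.089787170954475
  '88': 0.098439495708643
  '89': 0.107925600198332
  '90': 0.118325831459409
  '91': 0.12972827915556
  '92': 0.142229521695236
  '93': 0.155935444248037
  '94': 0.170962135589092
  '95': 0.187436871367692
  '96': 0.205499192128424
  '97': 0.225302085215631
  '98': 0.247013280571873
  '99': 0.270816671405781
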