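{"id":null,"format":"Biological Observation Matrix 1.0.0","format_url":"http://biom-format.org","type":"OTU table","generated_by":"fmtengraft 0.1.0","date":"2026-09-22T03:48:42","matrix_type":"sparse","matrix_element_type":"int","shape":[25,18],"rows":[{"id":"OTU001","metadata":{"taxonomy":["k__Bacteria","p__P2","c__C2","o__O2","f__F2","g__G001"]}},{"id":"OTU002","metadata":{"taxonomy":["k__Bacteria","p__P3","c__C3","o__O3","f__F3","g__G002"]}},{"id":"OTU003","metadata":{"taxonomy":["k__Bacteria","p__P4","c__C4","o__O4","f__F4","g__G003"]}},{"id":"OTU004","metadata":{"taxonomy":["k__Bacteria","p__P5","c__C5","o__O5","f__F5","g__G004"]}},{"id":"OTU005","metadata":{"taxonomy":["k__Bacteria","p__P6","c__C6","o__O6","f__F6","g__G005"]}},{"id":"OTU006","metadata":{"taxonomy":["k__Bacteria","p__P7","c__C7","o__O7","f__F7","g__G006"]}},{"id":"OTU007","metadata":{"taxonomy":["k__Bacteria","p__P1","c__C8","o__O8","f__F8","g__G007"]}},{"id":"OTU008","metadata":{"taxonomy":["k__Bacteria","p__P2","c__C9","o__O9","f__F9","g__G008"]}},{"id":"OTU009","metadata":{"taxonomy":["k__Bacteria","p__P3","c__C10","o__O10","f__F10","g__G009"]}},{"id":"OTU010","metadata":{"taxonomy":["k__Bacteria","p__P4","c__C11","o__O11","f__F11","g__G010"]}},{"id":"OTU011","metadata":{"taxonomy":["k__Bacteria","p__P5","c__C12","o__O12","f__F12","g__G011"]}},{"id":"OTU012","metadata":{"taxonomy":["k__Bacteria","p__P6","c__C13","o__O13","f__F13","g__G012"]}},{"id":"OTU013","metadata":{"taxonomy":["k__Bacteria","p__P7","c__C1","o__O14","f__F14","g__G013"]}},{"id":"OTU014","metadata":{"taxonomy":["k__Bacteria","p__P1","c__C2","o__O15","f__F15","g__G014"]}},{"id":"OTU015","metadata":{"taxonomy":["k__Bacteria","p__P2","c__C3","o__O16","f__F16","g__G015"]}},{"id":"OTU016","metadata":{"taxonomy":["k__Bacteria","p__P3","c__C4","o__O17","f__F17","g__G016"]}},{"id":"OTU017","metadata":{"taxonomy":["k__Bacteria","p__P4","c__C5","o__O1","f__F18","g__G017"]}},{"id":"OTU018","metadata":{"taxonomy":["k__Bacteria","p__P5","c__C6","o__O2","f__F19","g__G018"]}},{"id":"OTU019","metadata":{"taxonomy":["k__Bacteria","p__P6","c__C7","o__O3","f__F20","g__G019"]}},{"id":"OTU020","metadata":{"taxonomy":["k__Bacteria","p__P7","c__C8","o__O4","f__F21","g__G020"]}},{"id":"OTU021","metadata":{"taxonomy":["k__Bacteria","p__P1","c__C9","o__O5","f__F22","g__G021"]}},{"id":"OTU022","metadata":{"taxonomy":["k__Bacteria","p__P2","c__C10","o__O6","f__F23","g__G022"]}},{"id":"OTU023","metadata":{"taxonomy":["k__Bacteria","p__P3","c__C11","o__O7","f__F24","g__G023"]}},{"id":"OTU024","metadata":{"taxonomy":["k__Bacteria","p__P4","c__C12","o__O8","f__F25","g__G024"]}},{"id":"OTU025","metadata":{"taxonomy":["k__Bacteria","p__P5","c__C13","o__O9","f__F26","g__G025"]}}],"columns":[{"id":"DON1_donor","metadata":null},{"id":"DON2_donor","metadata":null},{"id":"P01_W-2","metadata":null},{"id":"P01_D0","metadata":null},{"id":"P01_W2","metadata":null},{"id":"P01_W6","metadata":null},{"id":"P02_W-2","metadata":null},{"id":"P02_D0","metadata":null},{"id":"P02_W2","metadata":null},{"id":"P02_W6","metadata":null},{"id":"P03_W-2","metadata":null},{"id":"P03_D0","metadata":null},{"id":"P03_W2","metadata":null},{"id":"P03_W6","metadata":null},{"id":"P04_W-2","metadata":null},{"id":"P04_D0","metadata":null},{"id":"P04_W2","metadata":null},{"id":"P04_W6","metadata":null}],"data":[[1,0,1],[2,0,76],[3,0,1],[4,0,13],[5,0,38],[6,0,3],[8,0,27],[9,0,12],[10,0,12],[13,0,3],[14,0,3],[15,0,25],[16,0,64],[17,0,14],[19,0,5],[20,0,82],[21,0,105],[22,0,21],[24,0,105],[0,1,26],[1,1,8],[2,1,4],[4,1,13],[5,1,18],[6,1,149],[7,1,1],[8,1,6],[9,1,37],[10,1,31],[11,1,4],[12,1,4],[14,1,7],[15,1,15],[16,1,3],[17,1,13],[18,1,301],[19,1,17],[20,1,11],[21,1,21],[22,1,1],[23,1,51],[1,2,34],[3,2,1],[4,2,86],[5,2,89],[6,2,7],[8,2,151],[9,2,138],[10,2,1],[11,2,6],[13,2,18],[14,2,22],[16,2,1],[17,2,3],[18,2,48],[19,2,1],[20,2,40],[21,2,8],[22,2,2],[1,3,20],[4,3,57],[5,3,118],[6,3,4],[7,3,1],[8,3,157],[9,3,139],[11,3,5],[13,3,29],[14,3,30],[17,3,3],[18,3,25],[19,3,2],[20,3,40],[21,3,2],[1,4,18],[2,4,33],[4,4,34],[5,4,59],[6,4,7],[8,4,94],[9,4,50],[10,4,5],[13,4,8],[14,4,40],[15,4,41],[16,4,37],[17,4,7],[18,4,9],[19,4,1],[20,4,72],[21,4,154],[22,4,11],[23,4,2],[24,4,82],[1,5,6],[2,5,25],[4,5,46],[5,5,33],[6,5,4],[8,5,59],[9,5,41],[10,5,9],[11,5,1],[13,5,4],[14,5,20],[15,5,72],[16,5,18],[17,5,3],[18,5,14],[19,5,4],[20,5,36],[21,5,142],[22,5,21],[24,5,83],[0,6,52],[1,6,64],[3,6,8],[4,6,49],[6,6,7],[8,6,5],[9,6,9],[10,6,47],[11,6,4],[12,6,37],[13,6,35],[14,6,11],[15,6,26],[16,6,179],[18,6,107],[19,6,14],[20,6,38],[23,6,46],[0,7,22],[1,7,59],[3,7,8],[4,7,33],[6,7,8],[8,7,1],[9,7,6],[10,7,45],[11,7,1],[12,7,59],[13,7,20],[14,7,10],[15,7,15],[16,7,99],[18,7,192],[19,7,8],[20,7,34],[23,7,35],[0,8,15],[1,8,27],[2,8,4],[3,8,9],[4,8,14],[5,8,6],[6,8,55],[7,8,1],[8,8,3],[9,8,19],[10,8,40],[11,8,2],[12,8,31],[13,8,22],[14,8,14],[15,8,72],[16,8,65],[17,8,2],[18,8,226],[19,8,31],[20,8,20],[21,8,3],[22,8,2],[23,8,61],[0,9,29],[1,9,23],[2,9,3],[3,9,10],[4,9,10],[5,9,11],[6,9,51],[7,9,1],[8,9,4],[9,9,21],[10,9,35],[11,9,6],[12,9,70],[13,9,36],[14,9,9],[15,9,28],[16,9,129],[17,9,10],[18,9,197],[19,9,11],[20,9,24],[21,9,10],[22,9,1],[23,9,36],[0,10,53],[1,10,37],[2,10,37],[3,10,83],[6,10,2],[7,10,25],[8,10,4],[9,10,167],[10,10,9],[11,10,152],[13,10,51],[14,10,1],[15,10,1],[17,10,21],[18,10,36],[21,10,20],[23,10,3],[24,10,1],[0,11,42],[1,11,17],[2,11,13],[3,11,163],[6,11,5],[7,11,18],[8,11,2],[9,11,122],[10,11,10],[11,11,81],[13,11,110],[14,11,4],[15,11,2],[17,11,62],[18,11,33],[21,11,22],[23,11,4],[24,11,3],[0,12,46],[1,12,51],[2,12,28],[3,12,126],[6,12,1],[7,12,22],[8,12,3],[9,12,133],[10,12,15],[11,12,53],[13,12,64],[14,12,2],[17,12,27],[18,12,32],[21,12,6],[23,12,1],[0,13,33],[1,13,27],[2,13,27],[3,13,154],[6,13,2],[7,13,52],[8,13,7],[9,13,78],[10,13,14],[11,13,106],[13,13,160],[14,13,4],[15,13,1],[17,13,34],[18,13,21],[19,13,3],[21,13,6],[23,13,1],[1,14,2],[2,14,19],[5,14,25],[6,14,38],[7,14,7],[8,14,96],[9,14,3],[10,14,108],[11,14,21],[12,14,7],[13,14,10],[14,14,109],[15,14,19],[17,14,59],[18,14,33],[19,14,55],[20,14,4],[21,14,2],[22,14,55],[23,14,2],[2,15,53],[5,15,9],[6,15,51],[7,15,3],[8,15,22],[9,15,7],[10,15,159],[11,15,7],[12,15,9],[13,15,5],[14,15,43],[15,15,6],[16,15,2],[17,15,51],[18,15,33],[19,15,49],[20,15,4],[21,15,1],[22,15,129],[0,16,2],[2,16,43],[5,16,35],[6,16,44],[7,16,1],[8,16,35],[9,16,5],[10,16,157],[11,16,10],[12,16,16],[13,16,3],[14,16,51],[15,16,6],[16,16,1],[17,16,26],[18,16,21],[19,16,28],[20,16,7],[21,16,2],[22,16,137],[2,17,41],[5,17,26],[6,17,33],[7,17,6],[8,17,41],[9,17,4],[10,17,281],[11,17,7],[12,17,5],[13,17,3],[14,17,102],[15,17,11],[17,17,23],[18,17,30],[19,17,46],[20,17,6],[21,17,4],[22,17,29]]}
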