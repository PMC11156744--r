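strain_id,MG,SP,MO3,MO3_t,MO5,MO5_t,MO7,MO7_t,BI,BI_t
MTCC-4511,59.3,6.5,75.0,60.0,88.6,70.3,95.1,77.2,70.3,57.0
MTCC-4565,62.4,1.5,57.2,49.1,76.6,61.1,89.9,71.5,68.2,55.7
MTCC-4543,50.3,5.9,67.4,55.2,80.0,63.4,85.4,67.5,62.1,52.0
MTCC-6097,51.7,4.4,23.6,29.1,64.4,53.4,81.7,64.7,60.5,51.1
MTCC-4111,68.9,0.4,32.9,35.0,64.8,53.6,68.9,56.1,60.0,50.8
MTCC-4537,37.7,9.9,83.6,66.1,83.7,66.2,86.4,68.4,58.4,49.8
MTCC-4581,44.2,1.3,60.0,58.3,74.8,59.9,78.8,62.6,55.9,48.4
MTCC-4568,57.7,0.4,58.8,50.1,64.5,53.4,68.7,56.0,55.8,48.3
MTCC-6288,27.6,18.4,82.0,64.9,82.6,65.3,86.2,68.2,55.7,48.3
MTCC-4575,49.0,12.8,56.8,48.9,69.8,56.7,70.3,57.0,55.0,48.3
MTCC-6289,16.8,7.5,83.2,65.8,87.1,69.0,93.8,75.6,54.1,47.4
MTCC-4542,16.0,19.1,70.4,57.0,72.9,58.6,82.8,65.5,49.8,44.9
MTCC-4535,10.5,2.5,76.9,61.3,80.0,63.4,81.5,64.5,45.0,42.1
MTCC-4549,44.2,2.3,48.3,48.9,62.8,52.4,73.5,59.0,53.4,46.9
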