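setup,kvp,cu_mm,pad,angle_deg,field_cm,measured_mGy,predicted_mGy,percent_error_printed
phantom,50,0,no,0,15,65.6,61.2,-6.6
phantom,80,0,no,0,15,179.8,171.8,-4.5
phantom,100,0,no,0,15,276.5,266.1,-3.8
phantom,50,0.2,no,0,15,13.0,10.9,-16.1
phantom,80,0.2,no,0,15,61.9,57.8,-6.7
phantom,100,0.2,no,0,15,108.2,101.7,-6.0
phantom,50,0.6,no,0,15,1.7,1.6,-6.5
phantom,80,0.6,no,0,15,21.5,19.9,-7.5
phantom,100,0.6,no,0,15,43.8,45.2,3.2
phantom_table,50,0,no,0,15,57.3,54.7,-4.6
phantom_table,80,0,no,0,15,175.8,162.2,-7.7
phantom_table,100,0,no,0,15,266.8,255.8,-4.1
phantom_table,50,0.2,no,0,15,12.0,10.4,-13.4
phantom_table,80,0.2,no,0,15,62.3,57.1,-8.3
phantom_table,100,0.2,no,0,15,110.6,102.1,-7.7
phantom_table,50,0.6,no,0,15,1.6,1.6,-4.4
phantom_table,80,0.6,no,0,15,22.2,20.3,-8.7
phantom_table,100,0.6,no,0,15,45.7,46.4,1.5
phantom_table_pad,50,0,no,0,15,49.9,47.8,-4.1
phantom_table_pad,80,0,no,0,15,151.8,142.7,-6.0
phantom_table_pad,100,0,no,0,15,229.3,225.5,-1.6
phantom_table_pad,50,0.2,no,0,15,10.3,9.2,-10.5
phantom_table_pad,80,0.2,no,0,15,57.3,50.6,-11.8
phantom_table_pad,100,0.2,no,0,15,101.0,90.4,-10.5
phantom_table_pad,50,0.6,no,0,15,1.5,1.4,-5.7
phantom_table_pad,80,0.6,no,0,15,20.2,17.9,-11.2
phantom_table_pad,100,0.6,no,0,15,41.4,41.0,-0.9
angular,80,0.2,no,0,5,45.2,48.1,6.6
angular,80,0.2,no,30,5,43.2,46.4,7.5
angular,80,0.2,no,60,5,36.9,36.9,-0.1
angular,80,0.2,yes,0,5,41.8,40.8,-2.5
angular,80,0.2,yes,30,5,40.7,38.5,-5.2
angular,80,0.2,yes,60,5,31.2,27.8,-11.0
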