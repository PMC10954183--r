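grain_id,group1,value1,dist2_1,prob1,group2,value2,dist2_2,prob2
Ala 0002,Ipomoea batatas,-0.80,32.87,0.78,Manihot esculenta,-2.08,35.43,0.22
Ala 0004,Ipomoea batatas,-3.89,26.33,0.56,Archeo,-4.15,26.86,0.43
Ala 0005,Artocarpus altilis,0.82,117.88,0.93,Ipomoea batatas,-2.08,123.67,0.05
Ala 0006,Dioscorea alata,18.65,146.02,1.00,Curcuma longa,3.15,177.01,0.00
Ala 0007,Artocarpus altilis,7.89,21.75,0.97,Manihot esculenta,4.32,28.90,0.03
Ala 0010,Ipomoea batatas,0.33,12.80,0.52,Manihot esculenta,0.23,13.00,0.47
Ala 0011,Inocarpus fagifer,-2.85,33.23,0.43,Ipomoea batatas,-3.06,33.64,0.35
Ala 0012,Spondias dulcis,-2.61,40.07,0.52,Archeo,-2.70,40.25,0.48
Ala 0013,Spondias dulcis,0.91,52.04,1.00,Archeo,-4.94,63.73,0.00
Ala 0014,Zingiber officinale,3.34,102.70,1.00,Archeo,-2.54,114.44,0.00
Ala 0015,Canna sp.,22.32,112.31,1.00,Musa sp.,0.69,155.57,0.00
Ala 0016,Xanthosoma sp.,-2.62,86.46,0.55,Ipomoea batatas,-2.89,86.99,0.42
Ala 0021,Spondias dulcis,0.04,31.26,0.98,Archeo,-3.76,38.86,0.02
Ala 0023,Spondias dulcis,5.13,20.88,1.00,Zingiber officinale,-3.27,37.69,0.00
Ala 0024,Ipomoea batatas,0.88,12.81,0.92,Manihot esculenta,-1.73,18.02,0.07
Ala 0027,Ipomoea batatas,0.46,10.45,0.57,Manihot esculenta,0.17,11.03,0.42
Ala 0037,Colocasia esculenta,26.16,106.89,1.00,Inocarpus fagifer,16.43,126.33,0.00
Ala 0039,Manihot esculenta,1.94,42.56,0.95,Ipomoea batatas,-1.13,48.71,0.04
Ala 0041,Canna sp.,3.51,75.19,0.97,Ipomoea batatas,0.11,81.99,0.03
Ala 0043,Artocarpus altilis,9.52,7.34,0.99,Manihot esculenta,4.47,17.43,0.01
Ala 0044,Ipomoea batatas,1.12,51.57,0.95,Archeo,-1.76,57.33,0.05
Ala 0045,Dioscorea alata,13.82,47.72,0.86,Spondias dulcis,11.99,51.37,0.14
Ala 0046,Zingiber officinale,2.23,53.18,0.99,Archeo,-2.74,63.12,0.01
Ala 0047,Zingiber officinale,5.95,31.18,1.00,Archeo,-0.52,44.11,0.00
Ala 0048,Spondias dulcis,1.95,33.15,0.94,Archeo,-0.81,38.67,0.06
Ala 0049,Manihot esculenta,0.35,48.60,0.81,Archeo,-1.57,52.45,0.12
Ala 0050,Archeo,0.46,41.65,0.98,Spondias dulcis,-3.69,49.96,0.02
Ala 0051,Zingiber officinale,4.91,37.00,0.98,Spondias dulcis,0.72,45.39,0.01
Ala 0052,Artocarpus altilis,35.38,148.82,1.00,Inocarpus fagifer,24.42,170.75,0.00
Ala 0053,Archeo,-2.98,71.02,0.52,Ipomoea batatas,-3.06,71.18,0.48
Ala 0055,Archeo,-0.64,31.85,0.98,Ipomoea batatas,-4.70,39.96,0.02
Ala 0056,Artocarpus altilis,4.99,8.92,0.95,Manihot esculenta,1.84,15.23,0.04
Ala 0057,Artocarpus altilis,15.79,33.33,0.85,Manihot esculenta,14.04,36.83,0.15
Ala 0058,Spondias dulcis,0.57,27.43,0.82,Archeo,-0.97,30.51,0.18
Ala 0060,Archeo,-2.27,16.51,0.95,Ipomoea batatas,-5.27,22.51,0.05
Ala 0061,Archeo,1.95,79.13,0.66,Curcuma longa,1.23,80.57,0.32
Ala 0063,Spondias dulcis,1.23,21.13,0.85,Archeo,-0.50,24.59,0.15
Ala 0064,Manihot esculenta,0.46,13.37,0.49,Ipomoea batatas,0.44,13.41,0.48
Ala 0065,Archeo,0.30,45.52,0.99,Ipomoea batatas,-4.88,55.86,0.01
Ala 0066,Ipomoea batatas,-1.32,95.14,0.65,Zingiber officinale,-1.96,96.43,0.34
Ala 0071,Archeo,0.52,76.75,0.99,Artocarpus altilis,-5.56,88.92,0.00
Ala 0072,Archeo,1.01,62.59,1.00,Ipomoea batatas,-6.41,77.42,0.00
Ala 0073,Ipomoea batatas,-0.77,55.16,0.73,Archeo,-1.76,57.12,0.27
Ala 0074,Archeo,-0.37,61.11,1.00,Xanthosoma sp.,-7.12,74.61,0.00
Ala 0075,Dioscorea alata,20.47,56.15,1.00,Spondias dulcis,9.52,78.06,0.00
Ala 0077,Archeo,-0.3897,33.45,0.93,Spondias dulcis,-3.00,38.67,0.07
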