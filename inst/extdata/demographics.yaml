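# Demographic probability tables for the synthetic cohort generator.
# Percentages are kept exactly as published by the Korean statistical
# sources (KOSIS Population and Housing Census 2015, Family Relationship
# System, Korean Red Cross blood statistics, MOHW smoking survey); vectors
# that do not sum to exactly 100 are renormalized proportionally at load
# time and the printed values retained for reporting.
family_names:
  labels: [Kim, Lee, Park, Jung, Choi, Jo, Kang, Yoon, Jang, Im, Shin, Yoo,
           Han, Oh, Seo, Jeon, Kwon, Hwang, An, Song, Other]
  percent: [21.56, 14.74, 8.46, 4.86, 4.72, 2.93, 2.56, 2.06, 2.06, 2.05,
            1.99, 1.94, 1.56, 1.54, 1.52, 1.51, 1.42, 1.41, 1.38, 1.38, 18.35]
age_bands:
  lower: [0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100]
  upper: [9, 19, 29, 39, 49, 59, 69, 79, 89, 99, 109]
  percent: [8.03, 9.40, 13.56, 14.10, 16.03, 16.62, 11.93, 6.80, 3.06, 0.40, 0.07]
regions:
  labels: [Seoul, Busan, Daegu, Incheon, Gwangju, Daejeon, Ulsan, Sejong,
           North Chungcheong, South Chungcheong, Gangwon, Gyeonggi,
           North Gyeongsang, South Gyeongsang, North Jeolla, South Jeolla, Jeju]
  percent: [18.5, 6.5, 4.7, 5.7, 2.9, 2.9, 2.2, 0.7, 3.1, 4.2, 2.9, 26.1,
            5.1, 6.4, 3.5, 3.5, 1.3]
blood_types:
  labels: [A, B, O, AB]
  percent: [34.0, 26.6, 27.5, 11.4]
smoking_percent: 21.5
illnesses: [cold, headache, gastritis, body ache, bruise]
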