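# Calendar definitions for Hamburg, 2019 (non-leap study year).
# School breaks, legal holidays and major public events; dates reconstructed
# from the 2019 Hamburg public calendar. A day may carry several flags.
year: 2019
breaks:
  - name: ski_break
    start: 2019-03-04
    end: 2019-03-15
  - name: pentecost_break
    start: 2019-05-13
    end: 2019-05-17
  - name: summer_break
    start: 2019-06-27
    end: 2019-08-07
  - name: autumn_break
    start: 2019-10-04
    end: 2019-10-18
  - name: christmas_break
    start: 2019-12-23
    end: 2019-12-31
holidays:
  - 2019-01-01   # New Year
  - 2019-04-19   # Good Friday
  - 2019-04-22   # Easter Monday
  - 2019-05-01   # Labor Day
  - 2019-05-30   # Ascension
  - 2019-06-10   # Whit Monday
  - 2019-10-03   # German Unity Day
  - 2019-10-31   # Reformation Day
  - 2019-12-25   # Christmas Day
  - 2019-12-26   # Boxing Day
events:
  - name: spring_dom
    start: 2019-03-22
    end: 2019-04-22
  - name: harbour_birthday
    start: 2019-05-10
    end: 2019-05-12
  - name: harley_days
    start: 2019-06-21
    end: 2019-06-23
  - name: schlagermove
    start: 2019-07-12
    end: 2019-07-13
  - name: summer_dom
    start: 2019-07-26
    end: 2019-08-25
  - name: christopher_street_day
    start: 2019-08-02
    end: 2019-08-04
  - name: winter_dom
    start: 2019-11-08
    end: 2019-12-08
  - name: christmas_markets
    start: 2019-11-25
    end: 2019-12-23
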